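# Demonstration federated query: patients homozygous for the rs2476601 risk
# allele, with all of their diagnosis codes.  Endpoint names and predicate
# IRIs match virtualize_bundle()'s defaults.
SELECT ?pid ?rsID ?genotype ?code
SERVICE genotype {
  ?g <http://example.org/biobank/genotypes#rsID> ?rsID .
  ?g <http://example.org/biobank/genotypes#genotype> ?genotype .
  ?g <http://example.org/biobank/genotypes#patientId> ?gpid .
  ?s <http://example.org/biobank/subjects#patientId> ?pid .
  FILTER(?pid = ?gpid)
}
SERVICE clinical {
  ?d <http://example.org/clinical/diagnoses#internalKey> ?demo .
  ?d <http://example.org/clinical/diagnoses#icd9_code> ?code .
  ?demo <http://example.org/clinical/demographics#clinicNumber> ?cn .
}
FILTER(?pid = ?cn)
FILTER(?rsID = "rs2476601")
FILTER(?genotype = "A:A")
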