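{"records":[{"accession":"SYN_ATERF1","recommended_name":"Ethylene-responsive transcription factor 1","alternative_names":["Ethylene-responsive element-binding factor 2","EREBP-2","Ethylene response factor 1"],"gene_names":["ERF1","ERF094","At4g17500","T6K21.50"],"short_names":["ATERF1","ERF-1","AtEBP2","EREB2"],"function_text":"Transcriptional activator that binds to the GCC-box pathogenesis-related promoter element. Acts downstream of the ethylene signaling cascade.","taxonomy":"Arabidopsis thaliana"},{"accession":"SYN_CNTN2","recommended_name":"Contactin-2","alternative_names":["Axonal glycoprotein TAG-1","Axonin-1","Transient axonal glycoprotein 1","TAX-1"],"gene_names":"CNTN2","short_names":[],"function_text":"In conjunction with another transmembrane protein, CNTNAP2, contributes to the organization of axonal domains at nodes of Ranvier by maintaining voltage-gated potassium channels at the juxtaparanodal region. May be involved in cell adhesion.","taxonomy":"Homo sapiens"}],"models":[{"model_id":"SYN_MODEL_ETHYLENE","curated":true,"reactions":[{"reaction_id":"rx1","participants":["ERF1","EIN3","EIL1","ACS2"]},{"reaction_id":"rx2","participants":["ATERF1","ERF1","CTR1","EIN2","ETR1"]}]}]}
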