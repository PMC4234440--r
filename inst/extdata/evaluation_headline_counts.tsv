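metric	value
nonredundant_resequencing_snps	24272905
shared_by_all_strains	802209
array_total	250000
related_species_polymorphic_snps	84933
passed_callrate_snps	189532
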