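name,block,quantity
bp_genome_total,genome,bp_total
bp_genA,genome,bp_A
bp_genC,genome,bp_C
bp_genG,genome,bp_G
bp_genT,genome,bp_T
fr_genA,genome,fr_A
fr_genC,genome,fr_C
fr_genG,genome,fr_G
fr_genT,genome,fr_T
genomic_shannon_score,genome,shannon
genomic_topological_score,genome,topological
genomic_chargaff_score_ct,genome,chargaff_ct
genomic_chargaff_score_pf,genome,chargaff_pf
n_cds_total,cds,n_total
bp_cds_total,cds,bp_total
bp_cdsA,cds,bp_A
bp_cdsC,cds,bp_C
bp_cdsG,cds,bp_G
bp_cdsT,cds,bp_T
fr_cdsA,cds,fr_A
fr_cdsC,cds,fr_C
fr_cdsG,cds,fr_G
fr_cdsT,cds,fr_T
cds_shannon_score,cds,shannon
cds_chargaff_score_ct,cds,chargaff_ct
cds_chargaff_score_pf,cds,chargaff_pf
n_rRNA_total,rRNA,n_total
bp_rRNA_total,rRNA,bp_total
bp_rRNAA,rRNA,bp_A
bp_rRNAC,rRNA,bp_C
bp_rRNAG,rRNA,bp_G
bp_rRNAT,rRNA,bp_T
fr_rRNAA,rRNA,fr_A
fr_rRNAC,rRNA,fr_C
fr_rRNAG,rRNA,fr_G
fr_rRNAT,rRNA,fr_T
rRNA_shannon_score,rRNA,shannon
rRNA_chargaff_score_ct,rRNA,chargaff_ct
rRNA_chargaff_score_pf,rRNA,chargaff_pf
n_tRNA_total,tRNA,n_total
bp_tRNA_total,tRNA,bp_total
bp_tRNAA,tRNA,bp_A
bp_tRNAC,tRNA,bp_C
bp_tRNAG,tRNA,bp_G
bp_tRNAT,tRNA,bp_T
fr_tRNAA,tRNA,fr_A
fr_tRNAC,tRNA,fr_C
fr_tRNAG,tRNA,fr_G
fr_tRNAT,tRNA,fr_T
tRNA_shannon_score,tRNA,shannon
tRNA_chargaff_score_ct,tRNA,chargaff_ct
tRNA_chargaff_score_pf,tRNA,chargaff_pf
n_ncRNA_total,ncRNA,n_total
bp_ncRNA_total,ncRNA,bp_total
bp_ncRNAA,ncRNA,bp_A
bp_ncRNAC,ncRNA,bp_C
bp_ncRNAG,ncRNA,bp_G
bp_ncRNAT,ncRNA,bp_T
ncRNA_shannon_score,ncRNA,shannon
ncRNA_chargaff_score_ct,ncRNA,chargaff_ct
ncRNA_chargaff_score_pf,ncRNA,chargaff_pf
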