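#!/usr/bin/env Rscript
# Copy-neutral LOH at the TP53 locus: simulate SNP profiles for a
# near-clonal CN-LOH tumor (variant VAF > 50%, no del(17p), all panel SNPs
# homozygous), a diploid heterozygous tumor, and a del(17p) case, then run
# the inference rule on each.

suppressMessages(library(tp53cll))
panel <- default_snp_panel()
seed <- 20230509L

loh <- clonal_architecture(list(list(fraction = 94, variants = "c.700T>C")),
                           het_snps = panel$snp_id[c(2, 4, 5, 7, 9, 11)],
                           cnloh = TRUE, del17p = "no")
prof <- simulate_snp_profile(loh, panel, depth = 2000L, seed = seed)
write.table(genotype_snps(prof), "results/snp_profile_cnloh.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(infer_cnloh(genotype_snps(prof), variant_vaf = 94, del17p = "no"))

het <- clonal_architecture(list(list(fraction = 60, variants = "c.700T>C")),
                           het_snps = panel$snp_id[c(2, 4, 5, 7, 9, 11)],
                           cnloh = FALSE, del17p = "no")
prof2 <- simulate_snp_profile(het, panel, depth = 2000L, seed = seed + 1L)
print(infer_cnloh(genotype_snps(prof2), variant_vaf = 30, del17p = "no"))

# del(17p): VAF above 50% reflects hemizygosity, not copy-neutral LOH
prof3 <- simulate_snp_profile(loh, panel, depth = 2000L, seed = seed + 2L)
print(infer_cnloh(genotype_snps(prof3), variant_vaf = 80, del17p = "yes"))
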