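test_that("classify_variant follows the SNP / INDEL / >50 bp PAV rule", {
  expect_identical(classify_variant("A", "G"), "SNP")
  expect_identical(classify_variant("A", c("G", "T")), "SNP")
  expect_identical(classify_variant("AT", "A"), "INDEL")
  expect_identical(classify_variant(strrep("A", 421), "A"), "PAV")
  expect_identical(classify_variant("A", strrep("T", 52)), "PAV")
  # boundary: exactly 50 bp difference is still an INDEL
  expect_identical(classify_variant(strrep("A", 51), "A"), "INDEL")
  # order-invariance over alts
  alts <- c("A", strrep("T", 80), "GG")
  ref <- "AC"
  for (p in list(1:3, 3:1, c(2, 1, 3)))
    expect_identical(classify_variant(ref, alts[p]), "PAV")
  # symbolic ALT classified via SVLEN
  expect_identical(classify_variant("A", "<DEL>", svlen = -400), "PAV")
  expect_identical(classify_variant("A", "<DEL>", svlen = -20), "INDEL")
  expect_error(classify_variant("", "A"), "empty")
  expect_error(classify_variant("A", character(0)), "empty")
})

test_that("read_vcf maps genotypes, masks hets, classifies and filters", {
  path <- write_mini_vcf(c(
    vcf_line("chr1", 50, "A", "G", c("0/0", "0/0", "1/1")),
    vcf_line("chr1", 150, "A", "G", c("0/0", "1/1", "./.")),
    vcf_line("chr1", 250, strrep("C", 401), "C", c("0/0", "0/1", "1|1"))))
  expect_message(vs <- read_vcf(path), "heterozygous")
  expect_identical(unname(vs$geno[2, ]), c(0L, 1L, NA_integer_))
  expect_identical(unname(vs$geno[3, ]), c(0L, NA_integer_, 1L))
  expect_identical(attr(vs, "n_het_masked"), 1L)
  expect_identical(vs$sites$variant_class, c("SNP", "SNP", "PAV"))
  # inclusive region filter keeps only the middle site
  reg <- suppressMessages(read_vcf(path, region = "chr1:100-200"))
  expect_identical(reg$sites$pos, 150L)
  reg2 <- suppressMessages(read_vcf(path, region = list("chr1", 100, 250)))
  expect_identical(reg2$sites$pos, c(150L, 250L))
})

test_that("read_vcf errors name the malformed line", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "s1"), collapse = "\t"),
               "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0",
               "chr1\t200\t.\tA\tG"), path)
  expect_error(read_vcf(path), "line 4")
  # triploid GT is an unsupported ploidy
  bad <- write_mini_vcf(vcf_line("chr1", 1, "A", "G", c("0/0/0", "0/0", "0/0")))
  expect_error(read_vcf(bad), "ploidy")
})

test_that("read_gff3 derives TSS by strand, sorts, and validates", {
  p <- write_mini_gff3(c(
    "chr1\tx\tgene\t9000\t9500\t.\t-\t.\tID=gB",
    "chr1\tx\tgene\t1000\t5000\t.\t+\t.\tID=gA",
    "chr1\tx\tmRNA\t1000\t5000\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\tx\tCDS\t1200\t1400\t.\t+\t0\tID=gA.1.c;Parent=gA.1"))
  genes <- read_gff3(p)
  expect_identical(vapply(genes, `[[`, "", "gene_id"), c("gA", "gB"))  # sorted
  expect_identical(genes[[1]]$tss, 1000L)
  expect_identical(genes[[1]]$cds, data.frame(start = 1200L, end = 1400L))
  expect_identical(genes[[2]]$tss, 9500L)  # minus strand: TSS at gene end
  bad <- write_mini_gff3(c(
    "chr1\tx\tgene\t1000\t5000\t.\t+\t.\tID=g1",
    "chr1\tx\tCDS\t4000\t6000\t.\t+\t0\tID=g1.c;Parent=g1"))
  expect_error(read_gff3(bad), "CDS")
  nostrand <- write_mini_gff3("chr1\tx\tgene\t1000\t5000\t.\t.\t.\tID=g1")
  expect_error(read_gff3(nostrand), "strand")
})

test_that("promoter_interval respects strand and clips at 1", {
  gp <- gene_model("g", "chr1", "+", 38000000L, 38005000L)
  expect_identical(promoter_interval(gp), c(37999000L, 37999999L))
  gm <- gene_model("g", "chr1", "-", 1000L, 5000L)
  expect_identical(promoter_interval(gm), c(5001L, 6000L))
  gc <- gene_model("g", "chr1", "+", 500L, 900L)
  expect_identical(promoter_interval(gc), c(1L, 499L))
  # + strand length property: realized length = min(length, tss - 1)
  for (tss in c(2L, 50L, 1000L, 5000L)) {
    g <- gene_model("g", "chr1", "+", tss, tss + 10L)
    iv <- promoter_interval(g, 1000)
    expect_identical(iv[2] - iv[1] + 1L, min(1000L, tss - 1L))
  }
})

test_that("read_phenotypes averages replicates and rejects bad rows", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("accession,trait,environment,value",
               "a1,SL,GST,10", "a1,SL,GST,12", "a2,SL,GST,NA", "a3,SL,GST,8"), p)
  expect_warning(ph <- read_phenotypes(p), "dropped 1")
  expect_identical(nrow(ph), 2L)
  expect_identical(ph$value[ph$accession == "a1"], 11)
  p2 <- tempfile(fileext = ".csv")
  writeLines("accession,trait,value\na1,SL,10", p2)
  expect_error(read_phenotypes(p2), "environment")
  p3 <- tempfile(fileext = ".csv")
  writeLines("accession,trait,environment,value", p3)
  expect_identical(nrow(read_phenotypes(p3)), 0L)
})

test_that("write/read round-trips the synthetic dataset exactly", {
  sim <- simulate_panel(sim_config(n_accessions = 40, n_null_genes = 2, causal_index = 2, seed = 3))
  for (gz in c(FALSE, TRUE)) {
    paths <- write_fixtures(sim, tempfile(), gzip = gz)
    vs <- read_vcf(paths[["vcf"]])
    expect_equal(vs$sites$pos, sim$variants$sites$pos)
    expect_equal(vs$sites$ref, sim$variants$sites$ref)
    expect_equal(vs$sites$variant_class, sim$variants$sites$variant_class)
    expect_identical(unname(vs$geno), unname(sim$variants$geno))
    expect_identical(vs$samples, sim$variants$samples)
    genes <- read_gff3(paths[["gff3"]])
    expect_identical(vapply(genes, `[[`, "", "gene_id"),
                     vapply(sim$genes, `[[`, "", "gene_id"))
    expect_identical(genes[[1]]$cds, sim$genes[[1]]$cds)
    expect_identical(genes[[1]]$tss, sim$genes[[1]]$tss)
    ph <- read_phenotypes(paths[["phenotypes"]])
    data.table::setkey(ph, accession, trait, environment)
    want <- data.table::as.data.table(sim$phenotypes)
    data.table::setkey(want, accession, trait, environment)
    expect_equal(ph$value, want$value)
  }
})

test_that("group summary reader validates n and sd", {
  p <- tempfile(fileext = ".csv")
  data.table::fwrite(table1_sd1("Guangzhou"), p)
  gs <- read_group_summaries(p)
  expect_identical(gs$n, c(25L, 91L, 28L, 46L))
  p2 <- tempfile(fileext = ".csv")
  writeLines("label,n,mean,sd\ng1,1,5,2", p2)
  expect_error(read_group_summaries(p2), "n >= 2")
})
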