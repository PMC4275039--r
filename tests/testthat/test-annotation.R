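# A hand-built two-chromosome toy: one plus-strand gene with codons
# ATG GGA AAA TAC TAA on chrA, and its minus-strand mirror on chrB.
toy_models <- function() {
  gene_models(
    genes = data.frame(gene_id = c("gA", "gB"), chrom = c("chrA", "chrB"),
                       strand = c("+", "-"), stringsAsFactors = FALSE),
    cds = data.frame(gene_id = c("gA", "gB"), start = c(2001, 2001),
                     end = c(2015, 2015), stringsAsFactors = FALSE))
}

toy_genome <- function() {
  cds <- "ATGGGAAAATACTAA"
  pad_l <- paste(rep("C", 2000), collapse = "")
  pad_r <- paste(rep("G", 2000), collapse = "")
  chrA <- paste0(pad_l, cds, pad_r)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  chrB <- paste0(pad_l, rc, pad_r)
  g <- Biostrings::DNAStringSet(c(chrA = chrA, chrB = chrB))
  g
}

test_that("upstream windows follow the strand and truncate at opposite bodies", {
  models <- gene_models(
    genes = data.frame(gene_id = c("g1", "g2"),
                       chrom = "chr1", strand = c("+", "-"),
                       stringsAsFactors = FALSE),
    cds = data.frame(gene_id = c("g1", "g2"), start = c(5001, 4002),
                     end = c(5300, 4700), stringsAsFactors = FALSE))
  lens <- c(chr1 = 10000L)
  # g2 occupies [4001,4700] on the minus strand inside g1's window
  regions <- extract_upstream_regions(models, lens)
  r1 <- regions[regions$gene_id == "g1", ]
  expect_equal(c(r1$start, r1$end, r1$length), c(4701, 5000, 300))
  expect_true(r1$truncated)
  # without the neighbour the window is the full 1 kb
  solo <- gene_models(models$genes[1, ], models$cds[models$cds$gene_id == "g1", ])
  r <- extract_upstream_regions(solo, lens)
  expect_equal(c(r$start, r$end, r$length), c(4001, 5000, 1000))
  # exclude mode drops the truncated gene entirely
  rex <- extract_upstream_regions(models, lens, mode = "exclude")
  expect_false("g1" %in% rex$gene_id)
  expect_error(extract_upstream_regions(models, c(chrX = 100L)), "unknown chromosome")
})

test_that("a gene starting at the chromosome edge has no upstream region", {
  models <- gene_models(
    genes = data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                       stringsAsFactors = FALSE),
    cds = data.frame(gene_id = "g1", start = 1, end = 300,
                     stringsAsFactors = FALSE))
  regions <- extract_upstream_regions(models, c(chr1 = 1000L))
  expect_equal(nrow(regions), 0)
})

test_that("coding variants classify by codon effect on both strands", {
  models <- toy_models()
  genome <- toy_genome()
  # plus strand: GGA -> GGC synonymous (third base of codon 2, pos 2006)
  expect_identical(
    classify_coding_variant(models, genome, "gA", "chrA", 2006, "A", "C"),
    "synonymous")
  # AAA -> GAA nonsynonymous (first base of codon 3, pos 2007)
  expect_identical(
    classify_coding_variant(models, genome, "gA", "chrA", 2007, "A", "G"),
    "nonsynonymous")
  # TAC -> TAA nonsense (third base of codon 4, pos 2012)
  expect_identical(
    classify_coding_variant(models, genome, "gA", "chrA", 2012, "C", "A"),
    "nonsense")
  # outside the CDS
  expect_identical(
    classify_coding_variant(models, genome, "gA", "chrA", 1500, "C", "T"),
    "non_coding")
  # same mutations through the minus-strand mirror: CDS position p maps to
  # genomic 2016 - p, alleles complemented
  expect_identical(
    classify_coding_variant(models, genome, "gB", "chrB", 2016 - 6, "T", "G"),
    "synonymous")
  expect_identical(
    classify_coding_variant(models, genome, "gB", "chrB", 2016 - 7, "T", "C"),
    "nonsynonymous")
  expect_error(
    classify_coding_variant(models, genome, "gA", "chrA", 2009, "G", "C"),
    "mismatch")
})

test_that("site opportunities match per-codon enumeration and conserve length", {
  models <- toy_models()
  genome <- toy_genome()
  opp <- compute_site_opportunities(models, genome)
  # independent enumeration over the codons ATG GGA AAA TAC TAA
  code <- Biostrings::GENETIC_CODE
  enum_syn <- function(cod) {
    s <- 0
    for (p in 1:3) for (b in c("A", "C", "G", "T")) {
      if (b == substr(cod, p, p)) next
      mut <- cod
      substr(mut, p, p) <- b
      if (code[[mut]] == code[[cod]]) s <- s + 1
    }
    s / 3
  }
  expected <- sum(vapply(c("ATG", "GGA", "AAA", "TAC", "TAA"), enum_syn, 0))
  expect_equal(opp$L_syn[opp$gene_id == "gA"], expected, tolerance = 1e-12)
  expect_equal(opp$L_syn + opp$L_repl, rep(15, 2), tolerance = 1e-12)
  # both strands see the same codons
  expect_equal(opp$L_syn[1], opp$L_syn[2], tolerance = 1e-12)
  # documented single-codon examples
  tab <- trnsel:::codon_opportunity_table()
  expect_equal(unname(tab["TTT"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(tab["GGG"]), 1, tolerance = 1e-12)
})

test_that("a minimal variant set fills exactly the expected cells", {
  models <- toy_models()
  genome <- toy_genome()
  regions <- extract_upstream_regions(models, genome)
  v <- data.frame(
    chrom = c("chrA", "chrA", "chrA"), pos = c(2006, 2007, 1500),
    ref = c("A", "A", "C"), alt = c("C", "G", "T"),
    status = c("polymorphic", "fixed", "fixed"), stringsAsFactors = FALSE)
  tab <- tabulate_mk_counts(models, regions, v, genome)
  gA <- tab[tab$gene_id == "gA", ]
  expect_equal(unlist(gA[, c("PS", "PR", "FS", "FR", "PC", "FC")]),
               c(PS = 1, PR = 0, FS = 0, FR = 1, PC = 0, FC = 1))
  expect_equal(sum(tab[tab$gene_id == "gB",
                       c("PS", "PR", "FS", "FR", "PC", "FC")]), 0)
})

test_that("tabulation assigns each variant to at most one cell", {
  fx <- emit_fixture_genome(n_genes = 8, seed = 101)
  regions <- extract_upstream_regions(fx$models, fx$genome)
  tab <- tabulate_mk_counts(fx$models, regions, fx$variants, fx$genome)
  total_counted <- sum(tab[, c("PS", "PR", "FS", "FR", "PC", "FC")])
  expect_lte(total_counted, nrow(fx$variants))
  # nonsense exclusion shows up in the log
  log <- attr(tab, "annotation_log")
  expect_true(any(log$reason == "nonsense_excluded"))
})

test_that("fixture roundtrip recovers planted counts exactly", {
  for (s in c(7, 21, 90)) {
    fx <- emit_fixture_genome(n_genes = 8, seed = s)
    regions <- extract_upstream_regions(fx$models, fx$genome)
    tab <- tabulate_mk_counts(fx$models, regions, fx$variants, fx$genome)
    exp <- fx$truth$counts
    m <- merge(tab, exp, by = "gene_id", suffixes = c("", "_exp"))
    for (cc in c("PS", "PR", "FS", "FR", "PC", "FC")) {
      expect_identical(as.integer(m[[cc]]), as.integer(m[[paste0(cc, "_exp")]]),
                       label = paste("column", cc, "seed", s))
    }
  }
})

test_that("counts are invariant under reverse-complementing the fixture", {
  fx <- emit_fixture_genome(n_genes = 8, seed = 33)
  regions <- extract_upstream_regions(fx$models, fx$genome)
  tab <- tabulate_mk_counts(fx$models, regions, fx$variants, fx$genome)
  mir <- mirror_fixture(fx)
  regions_m <- extract_upstream_regions(mir$models, mir$genome)
  tab_m <- tabulate_mk_counts(mir$models, regions_m, mir$variants, mir$genome)
  ord <- order(tab$gene_id); ord_m <- order(tab_m$gene_id)
  for (cc in c("PS", "PR", "FS", "FR", "PC", "FC", "L_syn", "L_repl", "L_reg")) {
    expect_equal(tab[[cc]][ord], tab_m[[cc]][ord_m], label = cc)
  }
})

test_that("truncation shortens the average regulatory region below the window", {
  fx <- emit_fixture_genome(n_genes = 8, seed = 55)
  regions <- extract_upstream_regions(fx$models, fx$genome)
  expect_lt(mean(regions$length), 1000)
  expect_true(any(regions$truncated))
})

test_that("ambiguous and conflicting variants are rejected or logged", {
  # two genes with overlapping CDS on opposite strands
  models <- gene_models(
    genes = data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                       strand = c("+", "-"), stringsAsFactors = FALSE),
    cds = data.frame(gene_id = c("g1", "g2"), start = c(31, 31),
                     end = c(45, 45), stringsAsFactors = FALSE))
  seqs <- paste0(paste(rep("C", 30), collapse = ""), "ATGGGAAAATACTAA",
                 paste(rep("G", 30), collapse = ""))
  genome <- Biostrings::DNAStringSet(c(chr1 = seqs))
  v <- data.frame(chrom = "chr1", pos = 36, ref = "A", alt = "C",
                  status = "polymorphic", stringsAsFactors = FALSE)
  tab <- tabulate_mk_counts(models, extract_upstream_regions(models, genome),
                            v, genome)
  expect_equal(sum(tab[, c("PS", "PR", "FS", "FR", "PC", "FC")]), 0)
  expect_identical(attr(tab, "annotation_log")$reason, "ambiguous_cds_overlap")
  # duplicated position with conflicting status
  v2 <- data.frame(chrom = "chr1", pos = c(10, 10), ref = c("C", "C"),
                   alt = c("T", "T"), status = c("polymorphic", "fixed"),
                   stringsAsFactors = FALSE)
  expect_error(trnsel:::validate_variants(v2), "conflicting")
})

test_that("GFF3, FASTA and variant TSV files roundtrip through disk", {
  dir <- tempfile("fx")
  fx <- emit_fixture_genome(n_genes = 6, seed = 12, dir = dir)
  models <- read_gene_models(fx$paths$gff)
  expect_identical(sort(models$genes$gene_id), sort(fx$models$genes$gene_id))
  expect_equal(models$cds[order(models$cds$start), "start"],
               fx$models$cds[order(fx$models$cds$start), "start"])
  genome <- Biostrings::readDNAStringSet(fx$paths$fasta)
  expect_identical(as.character(genome[[1]]), as.character(fx$genome[[1]]))
  v <- read_variants(fx$paths$variants)
  expect_identical(nrow(v), nrow(fx$variants))
  # the on-disk copies feed the same roundtrip
  names(genome) <- sub(" .*", "", names(genome))
  tab <- tabulate_mk_counts(models, extract_upstream_regions(models, genome),
                            v, genome)
  m <- merge(tab, fx$truth$counts, by = "gene_id", suffixes = c("", "_exp"))
  expect_identical(as.integer(m$PC), as.integer(m$PC_exp))
})
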