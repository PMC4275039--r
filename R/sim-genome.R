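# Emits a small annotated genome fixture with a fully known variant ledger:
# every planted variant occupies a concrete site whose annotation class and
# status are recorded, so the annotation stage can be tested for exact
# count recovery. The layout deliberately includes both strands, a gene at
# the chromosome start (zero-length upstream window), and a divergent
# opposite-strand pair whose upstream windows truncate each other.

BLOCK <- 4000L

#' Generate a synthetic genome, gene models and planted variant table
#'
#' Builds one chromosome carrying `n_genes` genes (alternating strands).
#' Gene 1 starts at position 1, so its upstream window is empty and it is
#' omitted from the regulatory regions; genes 2 and 3 form a divergent
#' opposite-strand pair whose 1 kb windows truncate each other and share an
#' intergenic stretch (planted regulatory variants are placed on the
#' correct side of the midpoint for nearest-start assignment). Planted
#' per-gene counts of synonymous / nonsynonymous / regulatory variants,
#' polymorphic and fixed, are drawn from small Poissons; one nonsense
#' variant is planted (recorded as excluded from counts). Variants are
#' realized one per codon: synonymous changes at the third position of a
#' fourfold-degenerate valine codon, replacement changes at the first
#' position of a lysine codon.
#'
#' @param n_genes number of genes (>= 4).
#' @param seed integer seed; the whole fixture is a deterministic function
#'   of it.
#' @param dir directory to write `genome.fa`, `genes.gff3`, `variants.tsv`
#'   and `truth.json`; `NULL` skips writing.
#' @param mean_count Poisson mean of planted counts per (class, status)
#'   cell.
#' @return list with `models` (a [gene_models()] object), `genome`
#'   (`DNAStringSet`), `variants` (data.frame), `truth` (list with the
#'   per-variant `ledger` and the expected per-gene `counts` table) and
#'   `paths` (when written).
#' @export
emit_fixture_genome <- function(n_genes = 8, seed = 1, dir = NULL,
                                mean_count = 2) {
  stopifnot(n_genes >= 4)
  withr::with_seed(seed, {
    layout <- fixture_layout(n_genes)
    plan <- fixture_plan(layout, mean_count)
    build_fixture(layout, plan, dir, seed)
  })
}

# Gene placement. Gene 1: plus strand at position 1. Genes 2/3: divergent
# overlap pair sharing a block. Remaining genes alternate strands, one per
# block, with full 1 kb windows.
fixture_layout <- function(n_genes) {
  rows <- list()
  n_cod <- function() sample(40:70, 1)
  # gene 1: CDS starts at base 1
  rows[[1]] <- data.frame(gene_id = "g01", strand = "+", n_codon = n_cod(),
                          cds_start = 1L)
  # genes 2 (plus) and 3 (minus) in block 2: g03 body inside g02's window
  off <- BLOCK
  rows[[2]] <- data.frame(gene_id = "g02", strand = "+", n_codon = n_cod(),
                          cds_start = off + 1501L)
  rows[[3]] <- data.frame(gene_id = "g03", strand = "-", n_codon = 100L,
                          cds_start = off + 601L)
  for (i in 4:n_genes) {
    off <- BLOCK * (i - 1)
    rows[[i]] <- data.frame(gene_id = sprintf("g%02d", i),
                            strand = if (i %% 2 == 0) "+" else "-",
                            n_codon = n_cod(), cds_start = off + 1501L)
  }
  lay <- do.call(rbind, rows)
  lay$cds_end <- lay$cds_start + 3L * lay$n_codon - 1L
  lay$chrom <- "chr1"
  lay
}

# planted counts per gene and class/status; regulatory variants only where a
# region will exist (not g01), with g02/g03 placements confined to their
# side of the shared-window midpoint
fixture_plan <- function(layout, mean_count) {
  n <- nrow(layout)
  plan <- data.frame(gene_id = layout$gene_id)
  for (col in c("PS", "FS", "PR", "FR", "PC", "FC")) {
    plan[[col]] <- rpois(n, mean_count)
  }
  plan[plan$gene_id == "g01", c("PC", "FC")] <- 0L
  # one codon per coding variant, leave headroom inside internal codons
  avail <- layout$n_codon - 2L
  need <- plan$PS + plan$FS + plan$PR + plan$FR
  over <- need > avail - 1L
  plan$PS[over] <- pmin(plan$PS[over], 2L); plan$FS[over] <- pmin(plan$FS[over], 2L)
  plan$PR[over] <- pmin(plan$PR[over], 2L); plan$FR[over] <- pmin(plan$FR[over], 2L)
  plan$nonsense <- 0L
  plan$nonsense[n] <- 1L  # one planted stop-gain, excluded from counts
  plan
}

build_fixture <- function(layout, plan, dir, seed) {
  chrom_len <- max(layout$cds_end) + 2500L
  bases <- c("A", "C", "G", "T")
  seqv <- sample(bases, chrom_len, replace = TRUE)

  safe_codons <- setdiff(names(Biostrings::GENETIC_CODE)
                         [Biostrings::GENETIC_CODE != "*"],
                         c("GTT", "AAA", "TAC"))  # reserved for planting
  ledger <- list()

  # write CDS codons and plant coding variants
  for (i in seq_len(nrow(layout))) {
    g <- layout[i, ]
    p <- plan[plan$gene_id == g$gene_id, ]
    n_internal <- g$n_codon - 2L
    codons <- c("ATG", sample(safe_codons, n_internal, replace = TRUE), "TAA")
    n_coding <- p$PS + p$FS + p$PR + p$FR + p$nonsense
    slots <- 1L + sample.int(n_internal, n_coding)  # internal codon indices
    classes <- rep(c("synonymous", "synonymous", "nonsynonymous",
                     "nonsynonymous", "nonsense"),
                   times = c(p$PS, p$FS, p$PR, p$FR, p$nonsense))
    statuses <- rep(c("polymorphic", "fixed", "polymorphic", "fixed",
                      "polymorphic"),
                    times = c(p$PS, p$FS, p$PR, p$FR, p$nonsense))
    for (j in seq_along(slots)) {
      k <- slots[j]
      spec <- switch(classes[j],
                     synonymous = list(codon = "GTT", within = 3L, alt = "C"),
                     nonsynonymous = list(codon = "AAA", within = 1L, alt = "G"),
                     nonsense = list(codon = "TAC", within = 3L, alt = "A"))
      codons[k] <- spec$codon
      cds_pos <- 3L * (k - 1L) + spec$within
      if (g$strand == "+") {
        gpos <- g$cds_start + cds_pos - 1L
        ref <- substr(spec$codon, spec$within, spec$within)
        alt <- spec$alt
      } else {
        gpos <- g$cds_end - cds_pos + 1L
        ref <- flip_base(substr(spec$codon, spec$within, spec$within))
        alt <- flip_base(spec$alt)
      }
      ledger[[length(ledger) + 1]] <- data.frame(
        chrom = g$chrom, pos = gpos, ref = ref, alt = alt,
        status = statuses[j], gene_id = g$gene_id, class = classes[j],
        excluded = classes[j] == "nonsense", stringsAsFactors = FALSE)
    }
    cds_seq <- paste(codons, collapse = "")
    if (g$strand == "-") {
      cds_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds_seq)))
    }
    seqv[g$cds_start:g$cds_end] <- strsplit(cds_seq, "")[[1]]
  }

  # regulatory variant positions: inside the (post-truncation) region, on
  # the right side of the shared-window midpoint for the divergent pair
  reg_window <- function(g) {
    if (g$gene_id == "g02") return(c(BLOCK + 1251L, BLOCK + 1500L))
    if (g$gene_id == "g03") return(c(BLOCK + 901L, BLOCK + 1150L))
    if (g$strand == "+") c(g$cds_start - 1000L, g$cds_start - 1L)
    else c(g$cds_end + 1L, g$cds_end + 1000L)
  }
  for (i in seq_len(nrow(layout))) {
    g <- layout[i, ]
    p <- plan[plan$gene_id == g$gene_id, ]
    n_reg <- p$PC + p$FC
    if (n_reg == 0) next
    w <- reg_window(g)
    pos <- sort(sample(seq.int(w[1], w[2]), n_reg))
    status <- rep(c("polymorphic", "fixed"), times = c(p$PC, p$FC))
    for (j in seq_len(n_reg)) {
      ref <- seqv[pos[j]]
      alt <- bases[match(ref, bases) %% 4 + 1]
      ledger[[length(ledger) + 1]] <- data.frame(
        chrom = g$chrom, pos = pos[j], ref = ref, alt = alt,
        status = status[j], gene_id = g$gene_id, class = "regulatory",
        excluded = FALSE, stringsAsFactors = FALSE)
    }
  }

  ledger <- do.call(rbind, ledger)
  ledger <- ledger[order(ledger$pos), ]
  rownames(ledger) <- NULL

  genome <- Biostrings::DNAStringSet(paste(seqv, collapse = ""))
  names(genome) <- "chr1"
  models <- gene_models(
    genes = data.frame(gene_id = layout$gene_id, chrom = layout$chrom,
                       strand = layout$strand, stringsAsFactors = FALSE),
    cds = data.frame(gene_id = layout$gene_id, start = layout$cds_start,
                     end = layout$cds_end, stringsAsFactors = FALSE))
  variants <- ledger[, c("chrom", "pos", "ref", "alt", "status")]

  # expected per-gene counts the annotation stage should reproduce
  keep <- ledger[!ledger$excluded, ]
  cell <- function(gid, cls, st) {
    sum(keep$gene_id == gid & keep$class == cls & keep$status == st)
  }
  expected <- do.call(rbind, lapply(layout$gene_id, function(gid) {
    data.frame(gene_id = gid,
               PS = cell(gid, "synonymous", "polymorphic"),
               PR = cell(gid, "nonsynonymous", "polymorphic"),
               FS = cell(gid, "synonymous", "fixed"),
               FR = cell(gid, "nonsynonymous", "fixed"),
               PC = cell(gid, "regulatory", "polymorphic"),
               FC = cell(gid, "regulatory", "fixed"),
               stringsAsFactors = FALSE)
  }))

  out <- list(models = models, genome = genome, variants = variants,
              truth = list(ledger = ledger, counts = expected, seed = seed,
                           layout = layout))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(fasta = file.path(dir, "genome.fa"),
                  gff = file.path(dir, "genes.gff3"),
                  variants = file.path(dir, "variants.tsv"),
                  truth = file.path(dir, "truth.json"))
    Biostrings::writeXStringSet(genome, paths$fasta)
    write_gene_models(models, paths$gff)
    write.table(variants, paths$variants, sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(out$truth[c("ledger", "counts", "seed")],
                         paths$truth, dataframe = "rows")
    out$paths <- paths
  }
  out
}
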