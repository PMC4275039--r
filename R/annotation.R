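# Variant annotation: turn gene models, genome sequence and labelled variant
# sites into per-gene MK count tables for the coding and putative
# cis-regulatory contexts. Coordinates are 1-based inclusive throughout
# (the GFF3 convention); FASTA/GFF3 I/O goes through Biostrings/rtracklayer.

#' Gene model container
#'
#' @param genes data.frame with `gene_id`, `chrom`, `strand` (+/-).
#' @param cds data.frame with `gene_id`, `start`, `end` (1-based inclusive,
#'   non-overlapping within a gene).
#' @return a `gene_models` list with sorted, validated components.
#' @export
gene_models <- function(genes, cds) {
  stopifnot(all(c("gene_id", "chrom", "strand") %in% names(genes)),
            all(c("gene_id", "start", "end") %in% names(cds)))
  if (anyDuplicated(genes$gene_id)) stop_input("duplicate gene identifiers")
  if (!all(genes$strand %in% c("+", "-"))) stop_input("strand must be + or -")
  if (!all(cds$gene_id %in% genes$gene_id)) stop_input("CDS for unknown gene")
  cds <- cds[order(cds$gene_id, cds$start), ]
  for (g in unique(cds$gene_id)) {
    iv <- cds[cds$gene_id == g, ]
    if (any(iv$end < iv$start)) stop_input("inverted CDS interval in ", g)
    if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)])) {
      stop_input("overlapping CDS intervals in ", g)
    }
    len <- sum(iv$end - iv$start + 1)
    if (len %% 3 != 0) stop_input("CDS length of ", g, " not divisible by 3")
  }
  structure(list(genes = genes, cds = cds), class = "gene_models")
}

#' Read and write gene models as GFF3
#'
#' The writer emits one `gene` feature per gene (ID = gene_id) and its `CDS`
#' features (Parent = gene_id); the reader accepts this layout back.
#'
#' @param path GFF3 file path.
#' @param models a `gene_models` object (writer).
#' @return `read_gene_models` returns a `gene_models` object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  gn <- gr[type == "gene"]
  genes <- data.frame(gene_id = as.character(gn$ID),
                      chrom = as.character(GenomicRanges::seqnames(gn)),
                      strand = as.character(GenomicRanges::strand(gn)),
                      stringsAsFactors = FALSE)
  cd <- gr[type == "CDS"]
  parent <- as.character(S4Vectors::unstrsplit(cd$Parent, ","))
  cds <- data.frame(gene_id = parent,
                    start = GenomicRanges::start(cd),
                    end = GenomicRanges::end(cd), stringsAsFactors = FALSE)
  gene_models(genes, cds)
}

#' @rdname read_gene_models
#' @export
write_gene_models <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  gn <- models$genes
  spans <- gene_spans(models)
  gn_gr <- GenomicRanges::GRanges(
    gn$chrom, IRanges::IRanges(spans$start[match(gn$gene_id, spans$gene_id)],
                               spans$end[match(gn$gene_id, spans$gene_id)]),
    strand = gn$strand, type = "gene", ID = gn$gene_id)
  cd <- models$cds
  strand_of <- setNames(gn$strand, gn$gene_id)
  chrom_of <- setNames(gn$chrom, gn$gene_id)
  cd_gr <- GenomicRanges::GRanges(
    chrom_of[cd$gene_id], IRanges::IRanges(cd$start, cd$end),
    strand = strand_of[cd$gene_id], type = "CDS",
    ID = paste0(cd$gene_id, ".cds", seq_len(nrow(cd))),
    Parent = cd$gene_id, phase = 0L)
  rtracklayer::export(c(gn_gr, cd_gr), path, format = "gff3")
  invisible(path)
}

# one row per gene: chrom, strand, span start/end, tss (start-codon-adjacent
# genomic position), total CDS length
gene_spans <- function(models) {
  agg_min <- tapply(models$cds$start, models$cds$gene_id, min)
  agg_max <- tapply(models$cds$end, models$cds$gene_id, max)
  g <- models$genes
  data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
             start = as.integer(agg_min[g$gene_id]),
             end = as.integer(agg_max[g$gene_id]),
             tss = ifelse(g$strand == "+", as.integer(agg_min[g$gene_id]),
                          as.integer(agg_max[g$gene_id])),
             stringsAsFactors = FALSE)
}

#' Extract putative cis-regulatory regions upstream of genes
#'
#' For each gene, the `window` bases immediately 5' of the start codon on
#' the gene's strand, clipped at chromosome ends. Any overlap with a gene
#' body on the complementary strand is removed: the retained region is the
#' maximal contiguous clear segment adjacent to the start codon (so an
#' opposite-strand gene sitting in the window truncates it, matching the
#' sub-window average lengths seen in practice). Genes whose region
#' truncates to length zero are omitted. Same-strand overlaps are not
#' truncated, only flagged. `mode = "exclude"` drops any gene with an
#' opposite-strand overlap instead of truncating.
#'
#' @param models a `gene_models` object.
#' @param genome a named `DNAStringSet` (for chromosome lengths) or a named
#'   integer vector of chromosome lengths.
#' @param window upstream window size in bases (default 1000).
#' @param mode `"truncate"` (default) or `"exclude"`.
#' @return data.frame with gene_id, chrom, strand, start, end, length,
#'   truncated, same_strand_overlap.
#' @export
extract_upstream_regions <- function(models, genome, window = 1000,
                                     mode = c("truncate", "exclude")) {
  mode <- match.arg(mode)
  stopifnot(inherits(models, "gene_models"), window > 0)
  chrlen <- chrom_lengths(genome)
  spans <- gene_spans(models)
  if (!all(spans$chrom %in% names(chrlen))) {
    stop_input("gene on unknown chromosome: ",
               paste(setdiff(spans$chrom, names(chrlen)), collapse = ", "))
  }
  out <- lapply(seq_len(nrow(spans)), function(i) {
    g <- spans[i, ]
    if (g$strand == "+") {
      ws <- max(1L, g$start - window); we <- g$start - 1L
    } else {
      ws <- g$end + 1L; we <- min(chrlen[[g$chrom]], g$end + window)
    }
    if (we < ws) return(NULL)
    others <- spans[spans$gene_id != g$gene_id & spans$chrom == g$chrom, ]
    opp <- others[others$strand != g$strand &
                    others$start <= we & others$end >= ws, ]
    same <- others[others$strand == g$strand &
                     others$start <= we & others$end >= ws, ]
    truncated <- nrow(opp) > 0
    if (truncated && mode == "exclude") return(NULL)
    if (truncated) {
      if (g$strand == "+") ws <- max(ws, max(opp$end) + 1L)
      else we <- min(we, min(opp$start) - 1L)
      if (we < ws) return(NULL)
    }
    data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
               start = ws, end = we, length = we - ws + 1L,
               truncated = truncated,
               same_strand_overlap = nrow(same) > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), length = integer(),
                      truncated = logical(), same_strand_overlap = logical())
  }
  rownames(out) <- NULL
  out
}

chrom_lengths <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    setNames(Biostrings::width(genome), names(genome))
  } else if (is.numeric(genome) && !is.null(names(genome))) {
    genome
  } else stop_input("'genome' must be a named DNAStringSet or length vector")
}

# spliced, strand-oriented CDS sequence of one gene (character scalar)
cds_sequence <- function(models, genome, gene_id) {
  g <- models$genes[models$genes$gene_id == gene_id, ]
  iv <- models$cds[models$cds$gene_id == gene_id, ]
  chrom_seq <- genome[[g$chrom]]
  parts <- lapply(seq_len(nrow(iv)), function(i) {
    Biostrings::subseq(chrom_seq, iv$start[i], iv$end[i])
  })
  s <- do.call(Biostrings::xscat, parts)
  if (g$strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

# per-codon synonymous opportunity (of 3 sites), for all 64 codons
codon_opportunity_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    code <- Biostrings::GENETIC_CODE
    bases <- c("A", "C", "G", "T")
    codons <- names(code)
    syn <- vapply(codons, function(cod) {
      aa <- code[[cod]]
      n_syn <- 0L
      for (p in 1:3) for (b in bases) {
        if (b == substr(cod, p, p)) next
        mut <- cod
        substr(mut, p, p) <- b
        if (code[[mut]] == aa) n_syn <- n_syn + 1L
      }
      n_syn / 3
    }, numeric(1))
    tab <<- syn
    tab
  }
})

#' Synonymous and replacement site opportunities per gene
#'
#' Nei-Gojobori-style counting: for each codon, the fraction of the nine
#' possible point mutations that preserve the encoded amino acid contributes
#' to `L_syn`, the remainder to `L_repl`; `L_syn + L_repl` equals the CDS
#' length exactly. Genes with an internal stop codon are flagged with a
#' warning.
#'
#' @param models a `gene_models` object.
#' @param genome a named `DNAStringSet`.
#' @return data.frame with gene_id, L_syn, L_repl, internal_stop.
#' @examples
#' # codon TTT contributes L_syn = 1/3; GGG contributes L_syn = 1
#' @export
compute_site_opportunities <- function(models, genome) {
  opp <- codon_opportunity_table()
  res <- lapply(models$genes$gene_id, function(gid) {
    s <- cds_sequence(models, genome, gid)
    n_cod <- nchar(s) / 3
    codons <- substring(s, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
    aas <- Biostrings::GENETIC_CODE[codons]
    internal_stop <- any(aas[-length(aas)] == "*")
    if (internal_stop) warning("internal stop codon in ", gid)
    syn <- sum(opp[codons])
    data.frame(gene_id = gid, L_syn = syn, L_repl = 3 * n_cod - syn,
               internal_stop = internal_stop, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Classify a coding point mutation
#'
#' Strand-aware codon lookup against the spliced CDS and translation under
#' the standard genetic code. Returns `"synonymous"`, `"nonsynonymous"`,
#' `"nonsense"` (stop gain or loss) or `"non_coding"` when the site falls
#' outside the gene's CDS. A reference allele disagreeing with the genome
#' sequence is a data-integrity error.
#'
#' @param models a `gene_models` object.
#' @param genome named `DNAStringSet`.
#' @param gene_id the gene to classify against.
#' @param chrom,pos variant location (1-based).
#' @param ref,alt single-nucleotide alleles on the plus strand of the
#'   genome.
#' @return character scalar.
#' @export
classify_coding_variant <- function(models, genome, gene_id, chrom, pos,
                                    ref, alt) {
  if (ref == alt) stop_input("ref and alt must differ")
  g <- models$genes[models$genes$gene_id == gene_id, ]
  if (nrow(g) != 1) stop_input("unknown gene ", gene_id)
  if (chrom != g$chrom) return("non_coding")
  iv <- models$cds[models$cds$gene_id == gene_id, ]
  hit <- which(iv$start <= pos & pos <= iv$end)
  if (length(hit) == 0) return("non_coding")
  genome_base <- as.character(Biostrings::subseq(genome[[chrom]], pos, pos))
  if (genome_base != ref) {
    stop_input("reference allele mismatch at ", chrom, ":", pos,
               " (genome ", genome_base, ", variant ", ref, ")")
  }
  # position within the spliced, strand-oriented CDS
  plus_offset <- sum(iv$end[seq_len(hit - 1)] - iv$start[seq_len(hit - 1)] + 1) +
    (pos - iv$start[hit] + 1)
  total <- sum(iv$end - iv$start + 1)
  cds_pos <- if (g$strand == "+") plus_offset else total - plus_offset + 1
  s <- cds_sequence(models, genome, gene_id)
  cod_i <- (cds_pos - 1) %/% 3 + 1
  within <- (cds_pos - 1) %% 3 + 1
  ref_codon <- substr(s, 3 * cod_i - 2, 3 * cod_i)
  alt_base <- if (g$strand == "+") alt else flip_base(alt)
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_base
  aa_ref <- Biostrings::GENETIC_CODE[[ref_codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
  if (aa_ref == aa_alt) "synonymous"
  else if (aa_ref == "*" || aa_alt == "*") "nonsense"
  else "nonsynonymous"
}

flip_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

#' Read a variant table
#'
#' Plain TSV with columns chrom, pos (1-based), ref, alt, status
#' (polymorphic/fixed).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_variants <- function(path) {
  v <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "status")
  if (!all(need %in% names(v))) {
    stop_input("variant table needs columns: ", paste(need, collapse = ", "))
  }
  validate_variants(v)
}

validate_variants <- function(v) {
  if (!all(v$status %in% c("polymorphic", "fixed"))) {
    stop_input("variant status must be 'polymorphic' or 'fixed'")
  }
  if (any(nchar(v$ref) != 1 | nchar(v$alt) != 1)) {
    stop_input("only single-nucleotide variants are supported")
  }
  if (any(v$ref == v$alt)) stop_input("ref and alt must differ")
  key <- paste(v$chrom, v$pos)
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    st <- tapply(v$status, key, function(x) length(unique(x)))
    if (any(st > 1)) {
      stop_input("conflicting polymorphic/fixed status at a duplicated position")
    }
  }
  v
}

#' Read variants from a VCF with an INFO status tag
#'
#' Adapter for VCF input: sites are taken from the fixed fields and the
#' polymorphic/fixed label from an INFO tag (default `STATUS`).
#'
#' @param path VCF path.
#' @param status_tag INFO field naming the status.
#' @return data.frame as from [read_variants()].
#' @export
read_variants_vcf <- function(path, status_tag = "STATUS") {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop_input("the VCF adapter needs the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  v <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt,
    status = as.character(VariantAnnotation::info(vcf)[[status_tag]]),
    stringsAsFactors = FALSE)
  validate_variants(v)
}

#' Tabulate per-gene MK counts from annotated variants
#'
#' Each variant is assigned to at most one (gene, class) cell. Sites inside
#' exactly one gene's CDS are classified with [classify_coding_variant()]:
#' synonymous changes fill PS/FS, nonsynonymous PR/FR; nonsense changes are
#' excluded from the counts but reported in the log. Sites inside CDS of
#' several genes are ambiguous and excluded. Remaining sites contained in
#' one regulatory region fill that gene's PC/FC; a site inside several
#' regions (divergent promoters) is assigned to the gene with the nearest
#' start codon (ties broken by gene identifier). Reference-mismatch sites
#' are skipped with a logged reason.
#'
#' @param models a `gene_models` object.
#' @param regions data.frame from [extract_upstream_regions()].
#' @param variants data.frame with chrom, pos, ref, alt, status.
#' @param genome named `DNAStringSet`.
#' @return an `mk_counts` data.frame (one row per gene, stable column order)
#'   with an `annotation_log` attribute listing excluded sites and reasons.
#' @export
tabulate_mk_counts <- function(models, regions, variants, genome) {
  stopifnot(inherits(models, "gene_models"))
  variants <- validate_variants(variants)
  genes <- models$genes$gene_id
  counts <- matrix(0L, nrow = length(genes), ncol = 6,
                   dimnames = list(genes, c("PS", "PR", "FS", "FR", "PC", "FC")))
  spans <- gene_spans(models)
  log <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    cds_hits <- models$cds[models$cds$start <= v$pos & v$pos <= models$cds$end, ]
    cds_genes <- unique(cds_hits$gene_id)
    cds_genes <- cds_genes[spans$chrom[match(cds_genes, spans$gene_id)] == v$chrom]
    status_col <- if (v$status == "polymorphic") "P" else "F"
    if (length(cds_genes) > 1) {
      log[[length(log) + 1]] <- data.frame(v, reason = "ambiguous_cds_overlap")
      next
    }
    if (length(cds_genes) == 1) {
      cls <- tryCatch(
        classify_coding_variant(models, genome, cds_genes, v$chrom, v$pos,
                                v$ref, v$alt),
        error = function(e) "ref_mismatch")
      if (cls == "ref_mismatch") {
        log[[length(log) + 1]] <- data.frame(v, reason = "ref_mismatch")
      } else if (cls == "nonsense") {
        log[[length(log) + 1]] <- data.frame(v, reason = "nonsense_excluded")
      } else if (cls == "synonymous") {
        counts[cds_genes, paste0(status_col, "S")] <-
          counts[cds_genes, paste0(status_col, "S")] + 1L
      } else if (cls == "nonsynonymous") {
        counts[cds_genes, paste0(status_col, "R")] <-
          counts[cds_genes, paste0(status_col, "R")] + 1L
      }
      next
    }
    reg_hits <- regions[regions$chrom == v$chrom & regions$start <= v$pos &
                          v$pos <= regions$end, ]
    if (nrow(reg_hits) == 0) {
      log[[length(log) + 1]] <- data.frame(v, reason = "unassigned")
      next
    }
    if (nrow(reg_hits) > 1) {
      tss <- spans$tss[match(reg_hits$gene_id, spans$gene_id)]
      dist <- abs(v$pos - tss)
      reg_hits <- reg_hits[order(dist, reg_hits$gene_id), ]
      log[[length(log) + 1]] <- data.frame(v, reason = paste0(
        "shared_region_assigned_", reg_hits$gene_id[1]))
    }
    gid <- reg_hits$gene_id[1]
    counts[gid, paste0(status_col, "C")] <- counts[gid, paste0(status_col, "C")] + 1L
  }
  opp <- compute_site_opportunities(models, genome)
  out <- data.frame(gene_id = genes, counts[, c("PS", "PR", "FS", "FR", "PC", "FC")],
                    L_syn = opp$L_syn[match(genes, opp$gene_id)],
                    L_repl = opp$L_repl[match(genes, opp$gene_id)],
                    L_reg = 0L, stringsAsFactors = FALSE, row.names = NULL)
  ridx <- match(genes, regions$gene_id)
  out$L_reg <- ifelse(is.na(ridx), 0L, regions$length[ridx])
  attr(out, "annotation_log") <- if (length(log)) do.call(rbind, log) else NULL
  class(out) <- c("mk_counts", "data.frame")
  out
}
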