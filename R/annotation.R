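#' Build merged gene models from transcript exon records
#'
#' Collapses all transcripts of each gene into a single gene-centric model:
#' overlapping exons of different isoforms are merged by union, and introns
#' are the gaps between merged exons. Any base that is exonic in any
#' transcript is exonic in the model (the exon-priority rule applied at the
#' model level: a read over a retained-intron region is counted as exonic).
#'
#' @param exons A data.frame of exon records with columns `gene_id`,
#'   `chrom`, `start`, `end` (0-based half-open, forward genomic strand),
#'   `strand` (`"+"`/`"-"`), and optionally `coding` (logical). One row per
#'   exon per transcript; a `transcript_id` column may be present but is
#'   not required.
#' @param coding_only Drop non-coding genes.
#' @return A named list of `gene_model` objects. Each has fields
#'   `gene_id`, `chromosome`, `strand`, `tss`, `exons` and `introns`
#'   (two-column matrices `start`/`end`, rows in transcription order),
#'   `exon_lengths`, `intron_lengths`, `n_introns`, `coding`.
#'   Malformed records (`end <= start`) are rejected with a warning.
#' @export
build_gene_models <- function(exons, coding_only = FALSE) {
  stopifnot(is.data.frame(exons),
            all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(exons)))
  bad <- exons$end <= exons$start
  if (any(bad)) {
    warning(sum(bad), " malformed exon record(s) with end <= start rejected")
    exons <- exons[!bad, , drop = FALSE]
  }
  if (!nrow(exons)) stop("no valid exon records")
  if (is.null(exons$coding)) exons$coding <- TRUE

  models <- lapply(split(exons, exons$gene_id), function(gx) {
    strand <- unique(gx$strand)
    chrom <- unique(gx$chrom)
    if (length(strand) != 1L || length(chrom) != 1L)
      stop("gene ", gx$gene_id[1], " spans multiple strands or chromosomes")
    merged <- IRanges::reduce(IRanges::IRanges(start = gx$start + 1L,
                                               end = gx$end))
    ex <- cbind(start = IRanges::start(merged) - 1L,
                end = IRanges::end(merged))
    n <- nrow(ex)
    intr <- if (n > 1L) {
      cbind(start = ex[-n, "end"], end = ex[-1L, "start"])
    } else {
      matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
    }
    if (strand == "-") {                       # transcription order
      ex <- ex[rev(seq_len(n)), , drop = FALSE]
      if (nrow(intr)) intr <- intr[rev(seq_len(nrow(intr))), , drop = FALSE]
    }
    tss <- if (strand == "+") ex[1L, "start"] else ex[1L, "end"]
    structure(list(gene_id = gx$gene_id[1], chromosome = chrom,
                   strand = strand, tss = unname(tss),
                   exons = ex, introns = intr,
                   exon_lengths = unname(ex[, "end"] - ex[, "start"]),
                   intron_lengths = unname(if (nrow(intr))
                     intr[, "end"] - intr[, "start"] else numeric(0)),
                   n_introns = nrow(intr), coding = any(gx$coding)),
              class = "gene_model")
  })
  if (coding_only) models <- Filter(function(g) g$coding, models)
  models
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s  %s:%s  %d exon(s), %d intron(s), tss %d%s\n",
              x$gene_id, x$chromosome, x$strand, length(x$exon_lengths),
              x$n_introns, x$tss, if (x$coding) "" else "  [non-coding]"))
  invisible(x)
}

#' Recover per-gene exon records from gene models
#'
#' Inverse of [build_gene_models()] for a merged model; building models
#' from the returned records reproduces the input models exactly.
#'
#' @param gene_models List of `gene_model` objects.
#' @return Exon record data.frame as accepted by [build_gene_models()].
#' @export
gene_models_to_exons <- function(gene_models) {
  do.call(rbind, lapply(gene_models, function(g) {
    data.frame(gene_id = g$gene_id, transcript_id = paste0(g$gene_id, ".t1"),
               chrom = g$chromosome, start = g$exons[, "start"],
               end = g$exons[, "end"], strand = g$strand, coding = g$coding,
               row.names = NULL)
  }))
}

# genomic interval of the window covering (r-1) bp each side of a boundary
.jxn_interval <- function(boundary, r) c(boundary - (r - 1L), boundary + r - 1L)

#' Enumerate the feature set of gene models
#'
#' Produces the per-gene features the quantifier counts reads into:
#' * `EXN` - each merged exon (ordinals in transcription order);
#' * `INT` - each intron; bases that are exonic in an overlapping gene on
#'   the same strand are excised, so an intron ordinal may span several
#'   blocks (rows share the ordinal);
#' * `INT3` - the 3'-most `d3_window` bp of each intron (the whole intron
#'   when shorter), used for the synthesis-rate proxy density;
#' * `INTBIN` - optionally, `n_bins` equal-length bins per intron
#'   (`ordinal2` = bin index, 5' to 3' in transcription direction) for
#'   slope fitting;
#' * `JXN5`/`JXN3` - windows of `r - 1` bp on each side of every
#'   exon->intron / intron->exon boundary; their effective length is
#'   `r - 1`;
#' * `SPL` - every intragenic exon pair (consecutive or not), `N*(N+1)/2`
#'   junctions for a gene with `N` introns; effective length
#'   `min(r - 1, exon lengths)`.
#'
#' @param gene_models A `gene_model` or list of them.
#' @param r Read length, bp (>= 2).
#' @param n_bins Number of equal-length intron bins to emit (0 = none).
#' @param d3_window 3'-intron window size, bp.
#' @return List with `features` (data.frame: `gene_id`, `class`, `ordinal`,
#'   `ordinal2`, `chrom`, `start`, `end`, `strand`, `length`, `boundary`)
#'   and `splice_library` (data.frame: `gene_id`, `exon_a`, `exon_b`,
#'   `key`, `consecutive`, `effective_length`).
#' @export
enumerate_features <- function(gene_models, r = 35L, n_bins = 0L,
                               d3_window = 10000L) {
  if (inherits(gene_models, "gene_model")) gene_models <- list(gene_models)
  stopifnot(r >= 2)
  # union of exonic bases per chrom/strand, for cross-gene intron masking
  all_ex <- do.call(rbind, lapply(gene_models, function(g)
    data.frame(chrom = g$chromosome, strand = g$strand,
               start = g$exons[, "start"], end = g$exons[, "end"],
               gene = g$gene_id)))
  feat_list <- vector("list", length(gene_models))
  spl_list <- vector("list", length(gene_models))

  for (k in seq_along(gene_models)) {
    g <- gene_models[[k]]
    n_ex <- length(g$exon_lengths)
    N <- g$n_introns
    rows <- list()
    row <- function(class, ordinal, start, end, length = end - start,
                    ordinal2 = NA_integer_, boundary = NA_real_)
      data.frame(gene_id = g$gene_id, class = class, ordinal = ordinal,
                 ordinal2 = ordinal2, chrom = g$chromosome, start = start,
                 end = end, strand = g$strand, length = length,
                 boundary = boundary)
    rows$exn <- row("EXN", seq_len(n_ex), g$exons[, "start"],
                    g$exons[, "end"])
    if (N > 0L) {
      # mask exonic bases of *other* genes out of this gene's introns
      other <- all_ex[all_ex$chrom == g$chromosome &
                        all_ex$strand == g$strand &
                        all_ex$gene != g$gene_id, , drop = FALSE]
      intr_ir <- IRanges::IRanges(start = g$introns[, "start"] + 1L,
                                  end = g$introns[, "end"])
      blocks <- if (nrow(other)) {
        mask <- IRanges::reduce(IRanges::IRanges(other$start + 1L, other$end))
        lapply(seq_len(N), function(i)
          IRanges::setdiff(intr_ir[i], mask))
      } else {
        lapply(seq_len(N), function(i) intr_ir[i])
      }
      int_rows <- do.call(rbind, lapply(seq_len(N), function(i) {
        b <- blocks[[i]]
        if (!length(b)) return(NULL)
        row("INT", i, IRanges::start(b) - 1L, IRanges::end(b))
      }))
      rows$int <- int_rows
      # 3'-most window of each full intron (transcription direction)
      w <- pmin(g$intron_lengths, d3_window)
      if (g$strand == "+") {
        rows$int3 <- row("INT3", seq_len(N), g$introns[, "end"] - w,
                         g$introns[, "end"])
      } else {
        rows$int3 <- row("INT3", seq_len(N), g$introns[, "start"],
                         g$introns[, "start"] + w)
      }
      if (n_bins > 0L) {
        rows$bins <- do.call(rbind, lapply(seq_len(N), function(i) {
          L <- g$intron_lengths[i]
          edges <- round(seq(0, L, length.out = n_bins + 1L))
          s5 <- edges[-(n_bins + 1L)]          # offsets from 5' end
          e5 <- edges[-1L]
          keep <- e5 > s5
          if (g$strand == "+") {
            st <- g$introns[i, "start"] + s5
            en <- g$introns[i, "start"] + e5
          } else {
            st <- g$introns[i, "end"] - e5
            en <- g$introns[i, "end"] - s5
          }
          row("INTBIN", i, st[keep], en[keep],
              ordinal2 = which(keep))
        }))
      }
      # junction windows: JXN5 at the exon->intron boundary (intron 5' end),
      # JXN3 at the intron->exon boundary (intron 3' end)
      b5 <- if (g$strand == "+") g$introns[, "start"] else g$introns[, "end"]
      b3 <- if (g$strand == "+") g$introns[, "end"] else g$introns[, "start"]
      rows$jxn5 <- row("JXN5", seq_len(N), pmax(0, b5 - (r - 1)), b5 + r - 1,
                       length = r - 1, boundary = b5)
      rows$jxn3 <- row("JXN3", seq_len(N), pmax(0, b3 - (r - 1)), b3 + r - 1,
                       length = r - 1, boundary = b3)
      pairs <- utils::combn(n_ex, 2L)
      lam <- pmin(r - 1, g$exon_lengths[pairs[1L, ]],
                  g$exon_lengths[pairs[2L, ]])
      rows$spl <- row("SPL", pairs[1L, ], NA_real_, NA_real_, length = lam,
                      ordinal2 = pairs[2L, ])
      spl_list[[k]] <- data.frame(
        gene_id = g$gene_id, exon_a = pairs[1L, ], exon_b = pairs[2L, ],
        key = sprintf("SPL|%s|%d|%d", g$gene_id, pairs[1L, ], pairs[2L, ]),
        consecutive = pairs[2L, ] == pairs[1L, ] + 1L,
        effective_length = lam)
    }
    feat_list[[k]] <- do.call(rbind, rows)
  }
  features <- do.call(rbind, feat_list)
  rownames(features) <- NULL
  splice_library <- do.call(rbind, spl_list)
  if (!is.null(splice_library)) rownames(splice_library) <- NULL
  list(features = features, splice_library = splice_library)
}

#' Mappability of features by exact k-mer uniqueness
#'
#' A genomic base is called mappable when at least one read-length window
#' covering it has a sequence that occurs exactly once in the genome
#' (counting both strands). Each feature's mappable-base count is the
#' number of its bases covered by some unique window. With no genome
#' supplied, every feature gets fraction 1.
#'
#' @param features Feature data.frame from [enumerate_features()].
#' @param genome A `Biostrings::DNAStringSet` (or path to a FASTA file)
#'   with one sequence per chromosome, or `NULL`.
#' @param r Read length, bp.
#' @return The feature data.frame with columns `mappable_bp` and
#'   `mappability` added. Features without genomic coordinates (SPL) and
#'   features on chromosomes missing from the genome (with a warning) get
#'   fraction 1.
#' @export
compute_mappability <- function(features, genome = NULL, r = 35L) {
  features$mappable_bp <- ifelse(is.na(features$start),
                                 features$length,
                                 features$end - features$start)
  features$mappability <- 1
  if (is.null(genome)) return(features)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))

  # genome-wide k-mer occurrence counts, both strands
  kmers_of <- function(seq) {
    s <- as.character(seq)
    n <- nchar(s) - r + 1L
    if (n < 1L) return(character(0))
    substring(s, seq_len(n), seq_len(n) + r - 1L)
  }
  fwd <- lapply(as.list(genome), kmers_of)
  rev <- lapply(as.list(Biostrings::reverseComplement(genome)), kmers_of)
  counts <- table(unlist(c(fwd, rev), use.names = FALSE))

  missing_warned <- character(0)
  for (chrom in unique(features$chrom)) {
    idx <- which(features$chrom == chrom & !is.na(features$start))
    if (!length(idx)) next
    if (!chrom %in% names(genome)) {
      missing_warned <- c(missing_warned, chrom)
      next
    }
    km <- fwd[[chrom]]
    uniq_starts <- which(counts[km] == 1L)           # 1-based window starts
    if (length(uniq_starts)) {
      cov <- IRanges::reduce(IRanges::IRanges(uniq_starts,
                                              uniq_starts + r - 1L))
    } else {
      cov <- IRanges::IRanges()
    }
    for (j in idx) {
      fj <- IRanges::IRanges(features$start[j] + 1L, features$end[j])
      features$mappable_bp[j] <- sum(IRanges::width(
        IRanges::intersect(cov, fj)))
      features$mappability[j] <-
        features$mappable_bp[j] / (features$end[j] - features$start[j])
    }
  }
  if (length(missing_warned))
    warning("no genome sequence for chromosome(s) ",
            paste(unique(missing_warned), collapse = ", "),
            "; mappability defaulted to 1")
  features
}
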