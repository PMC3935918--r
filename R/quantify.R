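#' Assign aligned reads to gene features
#'
#' Distributes uniquely-mapped, strand-specific reads over the feature set:
#' every aligned base lands in the unique `EXN`/`INT` block containing it
#' (exon priority over retained introns was already resolved when the gene
#' models were merged), and is additionally tallied into the overlay
#' features it falls in (`INT3` windows, `INTBIN` bins). Junction features
#' (`JXN5`/`JXN3`) receive only the bases of reads that actually cross the
#' boundary, within the window of read length minus one on each side.
#' Reads aligned to a splice-library key contribute their full length to
#' the corresponding `SPL` junction.
#'
#' @param reads Data.frame with columns `chrom` (chromosome name or splice
#'   library key), `start` (0-based), `length` (bp), `strand`.
#' @param features Feature data.frame from [enumerate_features()]
#'   (optionally after [compute_mappability()]).
#' @param splice_library Splice-library data.frame from
#'   [enumerate_features()], or `NULL`.
#' @return An object of class `feature_counts`: list with `features` (the
#'   input plus an `rdbp` column of overlapping read-bases), `splice`
#'   (library with `rdbp` and `n_reads`), `total_read_bases`,
#'   `intergenic_read_bases`.
#' @export
assign_reads <- function(reads, features, splice_library = NULL) {
  stopifnot(all(c("chrom", "start", "length", "strand") %in% names(reads)))
  features$rdbp <- 0
  total_rb <- sum(reads$length)

  rlen <- if (nrow(reads)) reads$length[1] else 0L
  spl_keys <- if (!is.null(splice_library)) splice_library$key else character(0)
  is_spl <- reads$chrom %in% spl_keys
  if (!is.null(splice_library)) {
    splice_library$n_reads <- as.integer(table(
      factor(reads$chrom[is_spl], levels = spl_keys)))
    splice_library$rdbp <- splice_library$n_reads * rlen
    sel <- features$class == "SPL"
    m <- match(paste(features$gene_id[sel], features$ordinal[sel],
                     features$ordinal2[sel]),
               paste(splice_library$gene_id, splice_library$exon_a,
                     splice_library$exon_b))
    features$rdbp[sel] <- splice_library$rdbp[m]
  }

  gr_reads <- reads[!is_spl, , drop = FALSE]
  hit_any <- rep(FALSE, nrow(gr_reads))
  if (nrow(gr_reads)) {
    rgr <- GenomicRanges::GRanges(gr_reads$chrom,
                                  IRanges::IRanges(gr_reads$start + 1L,
                                                   gr_reads$start +
                                                     gr_reads$length),
                                  strand = gr_reads$strand)
    genomic <- which(!is.na(features$start) & features$class != "SPL")
    fgr <- GenomicRanges::GRanges(features$chrom[genomic],
                                  IRanges::IRanges(features$start[genomic] + 1L,
                                                   features$end[genomic]),
                                  strand = features$strand[genomic])
    ov <- GenomicRanges::findOverlaps(rgr, fgr, ignore.strand = FALSE)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    ovw <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(rgr)[qh], IRanges::ranges(fgr)[sh]))
    fi <- genomic[sh]
    cls <- features$class[fi]
    # junction features take only boundary-crossing reads
    is_jxn <- cls %in% c("JXN5", "JXN3")
    if (any(is_jxn)) {
      b <- features$boundary[fi[is_jxn]]
      rs <- gr_reads$start[qh[is_jxn]]
      re <- rs + gr_reads$length[qh[is_jxn]]
      crosses <- rs < b & re > b
      drop <- which(is_jxn)[!crosses]
      if (length(drop)) {
        qh <- qh[-drop]; fi <- fi[-drop]; ovw <- ovw[-drop]
        cls <- features$class[fi]
      }
    }
    agg <- tapply(ovw, fi, sum)
    features$rdbp[as.integer(names(agg))] <- as.numeric(agg)
    hit_any[unique(qh[cls %in% c("EXN", "INT")])] <- TRUE
  }
  intergenic_rb <- sum(gr_reads$length[!hit_any])
  structure(list(features = features, splice = splice_library,
                 total_read_bases = total_rb,
                 intergenic_read_bases = intergenic_rb),
            class = "feature_counts")
}

#' Normalize feature counts to read densities
#'
#' Converts read-base counts to densities normalized to a standard library
#' of 10 million reads of 35 bp:
#' `D = (rdbp / mappable_bp) * (1e7 * 35) / total_aligned_read_bases`.
#' Density is therefore invariant under library-size rescaling, and
#' normalizing a library that is already standard-sized is the identity.
#' Per-gene class densities pool read-bases over all features of the class
#' before dividing by the pooled mappable bases (length-weighted
#' averaging). Divide densities by 0.35 to obtain RPKM.
#'
#' @param counts A `feature_counts` object (or a `synthetic_dataset`).
#' @param total_read_bases Total aligned read-bases in the library;
#'   defaults to the value recorded in `counts`.
#' @param standard_read_bases Read-bases of the standard library
#'   (default `1e7 * 35`).
#' @return An object of class `density_table`: list with
#'   `features` (per-feature `density`, `NA` where no mappable bases),
#'   `genes` (per-gene `D_EXN`, `D_INT`, `D_5SS`, `D_3SS`, `D_SPL`),
#'   `splice`, `scale`, `total_read_bases`.
#' @export
normalize_densities <- function(counts, total_read_bases = NULL,
                                standard_read_bases = 1e7 * 35) {
  stopifnot(inherits(counts, "feature_counts"))
  if (is.null(total_read_bases)) total_read_bases <- counts$total_read_bases
  if (total_read_bases <= 0) stop("total_read_bases must be positive")
  scale <- standard_read_bases / total_read_bases

  f <- counts$features
  if (is.null(f$mappability)) f$mappability <- 1
  bp <- f$length * f$mappability
  f$density <- ifelse(bp > 0, f$rdbp / bp * scale, NA_real_)
  f$excluded <- bp <= 0

  cls_map <- c(EXN = "D_EXN", INT = "D_INT", JXN5 = "D_5SS",
               JXN3 = "D_3SS", SPL = "D_SPL")
  sub <- f[f$class %in% names(cls_map) & bp > 0, , drop = FALSE]
  sub_bp <- sub$length * sub$mappability
  key <- interaction(sub$gene_id, sub$class, drop = TRUE)
  gsum <- data.frame(gene_id = tapply(sub$gene_id, key, `[`, 1),
                     class = tapply(as.character(sub$class), key, `[`, 1),
                     D = as.numeric(tapply(sub$rdbp, key, sum) /
                                      tapply(sub_bp, key, sum)) * scale)
  genes <- stats::reshape(gsum, idvar = "gene_id", timevar = "class",
                          direction = "wide")
  names(genes) <- ifelse(names(genes) == "gene_id", "gene_id",
                         cls_map[sub("^D\\.", "", names(genes))])
  rownames(genes) <- NULL

  spl <- counts$splice
  if (!is.null(spl) && !is.null(spl$rdbp))
    spl$density <- spl$rdbp / spl$effective_length * scale

  structure(list(features = f, genes = genes, splice = spl, scale = scale,
                 total_read_bases = total_read_bases),
            class = "density_table")
}

#' Fraction of splice-junction reads joining consecutive exons
#'
#' The steady-state model treats each intron as spliced independently
#' between adjacent exons; this diagnostic measures how often that holds.
#' Non-consecutive junctions supported by fewer than `min_reads_nc` reads
#' are treated as noise and excluded from the tally.
#'
#' @param counts A `feature_counts` object with splice-library counts.
#' @param min_reads_nc Minimum reads for a non-consecutive junction to be
#'   counted (default 2).
#' @return List with `fraction` (genome-wide consecutive fraction, `NA`
#'   when there are no splice reads), `per_gene` (data.frame), and
#'   `skipped_per_exon` (detectably-skipped fraction per internal exon).
#' @export
consecutive_splice_fraction <- function(counts, min_reads_nc = 2L) {
  stopifnot(inherits(counts, "feature_counts"))
  spl <- counts$splice
  if (is.null(spl) || !nrow(spl)) stop("no splice library counts available")
  n <- spl$n_reads
  counted <- spl$consecutive | n >= min_reads_nc
  use <- counted & n > 0
  tot <- sum(n[use])
  frac <- if (tot > 0) sum(n[use & spl$consecutive]) / tot else NA_real_

  pg <- do.call(rbind, lapply(split(spl[use, , drop = FALSE],
                                    spl$gene_id[use]), function(s) {
    t <- sum(s$n_reads)
    data.frame(gene_id = s$gene_id[1], n_reads = t,
               fraction = if (t > 0) sum(s$n_reads[s$consecutive]) / t
                          else NA_real_)
  }))
  # per internal exon: reads skipping it vs reads including it
  spe <- do.call(rbind, lapply(split(spl, spl$gene_id), function(s) {
    n_ex <- max(s$exon_b)
    if (n_ex < 3L) return(NULL)
    do.call(rbind, lapply(2:(n_ex - 1L), function(e) {
      skip <- s$exon_a < e & s$exon_b > e & s$n_reads >= min_reads_nc
      incl <- (s$exon_b == e | s$exon_a == e) & s$consecutive
      ns <- sum(s$n_reads[skip]); ni <- sum(s$n_reads[incl])
      data.frame(gene_id = s$gene_id[1], exon = e,
                 skipped_fraction = if (ns + ni > 0) ns / (ns + ni)
                                    else NA_real_)
    }))
  }))
  list(fraction = frac, per_gene = pg, skipped_per_exon = spe)
}

#' Flag retained or shortened introns from splice-site densities
#'
#' A retained intron (or an alternative splice site that shortens the
#' annotated intron) makes the 5' and 3' splice-site features part of a
#' long-lived molecule, raising their densities from the intronic level
#' toward the exonic level. An intron is flagged when both splice-site
#' densities are closer, on the log scale, to the gene's exon density than
#' to its intron density; flagged introns are excluded from model fitting.
#'
#' @param density A `density_table`.
#' @return Data.frame with `gene_id`, `ordinal`, `D_5SS`, `D_3SS`, `D_INT`,
#'   `D_EXN`, `flagged`. Genes with zero exon density produce no flags
#'   (with a warning). A half-read pseudocount per feature keeps zero
#'   densities finite on the log scale.
#' @export
retained_intron_filter <- function(density) {
  stopifnot(inherits(density, "density_table"))
  f <- density$features
  g <- density$genes
  per_int <- function(cls) {
    s <- f[f$class == cls, c("gene_id", "ordinal", "density", "length")]
    agg <- stats::aggregate(cbind(density, length) ~ gene_id + ordinal,
                            data = s, FUN = mean)
    agg
  }
  j5 <- per_int("JXN5"); j3 <- per_int("JXN3"); it <- per_int("INT")
  m <- merge(merge(j5, j3, by = c("gene_id", "ordinal"),
                   suffixes = c("_5", "_3")), it,
             by = c("gene_id", "ordinal"))
  m$D_EXN <- g$D_EXN[match(m$gene_id, g$gene_id)]
  no_exn <- is.na(m$D_EXN) | m$D_EXN <= 0
  if (any(no_exn))
    warning(length(unique(m$gene_id[no_exn])),
            " gene(s) with zero exonic density: introns not classifiable")
  # half-read pseudocount on the feature's own length scale
  eps <- 0.5 * density$scale * 35 / pmax(m$length, 1)
  l5 <- log(m$density_5 + eps); l3 <- log(m$density_3 + eps)
  li <- log(m$density + eps); le <- log(m$D_EXN + eps)
  m$flagged <- !no_exn &
    abs(l5 - le) < abs(l5 - li) & abs(l3 - le) < abs(l3 - li)
  out <- data.frame(gene_id = m$gene_id, ordinal = m$ordinal,
                    D_5SS = m$density_5, D_3SS = m$density_3,
                    D_INT = m$density, D_EXN = m$D_EXN, flagged = m$flagged)
  out[order(out$gene_id, out$ordinal), ]
}
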