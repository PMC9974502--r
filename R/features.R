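# Chromosome-level statistics: tau expression breadth, observed/expected
# interchromosomal Hi-C contact enrichment, relative ChIP level of repeat
# classes, and multicopy-gene (amplicon) expression normalisation.

#' Construct an expression matrix
#'
#' @param values Numeric matrix, genes in rows, tissues in columns; values on
#'   a nonnegative TPM-like scale.
#' @return The matrix with class `expression_matrix`.
#' @export
expression_matrix <- function(values) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), ncol(values) >= 1)
  if (any(values < 0)) stop("expression values must be >= 0", call. = FALSE)
  structure(values, class = c("expression_matrix", "matrix", "array"))
}

#' Read a genes x tissues expression table (TSV with header and gene-id
#' first column)
#'
#' @param path Path to the file.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m)
}

#' Tau tissue-specificity index
#'
#' For a gene with expression `x_1..x_n` over `n >= 2` tissues,
#' `tau = sum_i (1 - x_i / max(x)) / (n - 1)`. Tau is 0 for a uniformly
#' expressed (housekeeping-like) gene and 1 for strict single-tissue
#' expression, and is invariant to rescaling a gene's profile.
#'
#' @param expr An [expression_matrix()] (or numeric matrix), genes x tissues.
#' @param log_transform Compute tau on `log2(x + 1)` instead of the linear
#'   scale (default `FALSE`).
#' @return Named numeric vector of tau values in `[0, 1]`; genes with
#'   all-zero expression are `NA` (undefined) and their count is reported via
#'   a message.
#' @examples
#' tau(matrix(c(8, 2, 2), nrow = 1))  # 0.75
#' @export
tau <- function(expr, log_transform = FALSE) {
  m <- unclass(as.matrix(expr))
  if (ncol(m) < 2) stop("tau requires >= 2 tissues", call. = FALSE)
  if (any(m < 0)) stop("expression values must be >= 0", call. = FALSE)
  if (log_transform) m <- log2(m + 1)
  mx <- apply(m, 1L, max)
  out <- rowSums(1 - m / ifelse(mx > 0, mx, NA)) / (ncol(m) - 1)
  undef <- mx == 0
  if (any(undef)) {
    out[undef] <- NA_real_
    message(sum(undef), " gene(s) with all-zero expression excluded from tau")
  }
  stats::setNames(out, rownames(m))
}

#' Construct a binned Hi-C contact matrix
#'
#' @param values Symmetric nonnegative numeric matrix of normalised contact
#'   counts between bins.
#' @param bins data.frame with columns `chrom`, `index` (and optionally
#'   `start`), one row per matrix row/column, in order.
#' @param bin_size Bin size in bp (default 40000).
#' @param pericentromeric Logical per-bin mask flagging pericentromeric
#'   heterochromatin bins (default all `FALSE`).
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(values, bins, bin_size = 40000L,
                           pericentromeric = NULL) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), nrow(values) == ncol(values),
            is.data.frame(bins), nrow(bins) == nrow(values),
            all(c("chrom", "index") %in% names(bins)))
  if (any(values < 0)) stop("contact counts must be >= 0", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-8 * max(1, max(abs(values))))
    stop("contact matrix must be symmetric", call. = FALSE)
  if (is.null(pericentromeric)) pericentromeric <- rep(FALSE, nrow(bins))
  stopifnot(length(pericentromeric) == nrow(bins))
  structure(list(values = values, bins = bins, bin_size = bin_size,
                 pericentromeric = as.logical(pericentromeric)),
            class = "contact_matrix")
}

#' Read a sparse-text contact matrix
#'
#' Expects a 3-column TSV `bin_i  bin_j  count` (1-based bin indices, upper
#' or lower triangle or both; entries are symmetrised) and a bin table TSV
#' with header columns `chrom`, `index`, `start`.
#'
#' @param path Path to the sparse contact dump.
#' @param bins_path Path to the bin table.
#' @param bin_size Bin size in bp.
#' @param pch_bed Optional path to a BED file of pericentromeric intervals;
#'   bins overlapping any interval are masked.
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(path, bins_path, bin_size = 40000L,
                                pch_bed = NULL) {
  bins <- utils::read.delim(bins_path)
  stopifnot(all(c("chrom", "index") %in% names(bins)))
  n <- nrow(bins)
  sp <- utils::read.delim(path, header = FALSE,
                          col.names = c("i", "j", "count"))
  if (any(sp$i < 1 | sp$i > n | sp$j < 1 | sp$j > n))
    stop("bin index out of range", call. = FALSE)
  m <- matrix(0, n, n)
  m[cbind(sp$i, sp$j)] <- sp$count
  up <- upper.tri(m) & t(m) != 0 & m == 0
  m[up] <- t(m)[up]
  lo <- lower.tri(m) & t(m) != 0 & m == 0
  m[lo] <- t(m)[lo]
  pch <- rep(FALSE, n)
  if (!is.null(pch_bed) && "start" %in% names(bins)) {
    iv <- utils::read.delim(pch_bed, header = FALSE,
                            col.names = c("chrom", "start", "end"))
    for (k in seq_len(nrow(iv)))
      pch <- pch | (bins$chrom == iv$chrom[k] &
                      bins$start < iv$end[k] &
                      bins$start + bin_size > iv$start[k])
  }
  contact_matrix(m, bins, bin_size, pch)
}

#' Interchromosomal contact enrichment
#'
#' For every chromosome pair, compares observed trans (interchromosomal)
#' contacts `O_ab` to the expectation under random trans contact placement,
#' `E_ab` proportional to `T_a * T_b` where `T_a` is chromosome `a`'s total
#' trans contacts, rescaled so that the summed expectation equals the summed
#' observation. Cis (intrachromosomal) contacts never enter the marginals.
#' Ratios are log2-transformed.
#'
#' @param m A [contact_matrix()].
#' @param exclude_pch Drop pericentromeric bins before summing (default
#'   `TRUE`), restricting the statistic to euchromatin.
#' @return An object of class `pair_enrichment`: data.frame `chrom_a`,
#'   `chrom_b`, `observed`, `expected`, `log2_ratio` for all unordered pairs
#'   (a < b). Pairs involving a chromosome with zero trans contacts have
#'   `NA` ratios.
#' @export
contact_enrichment <- function(m, exclude_pch = TRUE) {
  stopifnot(inherits(m, "contact_matrix"))
  keep <- if (exclude_pch) !m$pericentromeric else rep(TRUE, nrow(m$bins))
  v <- m$values[keep, keep, drop = FALSE]
  chrom <- m$bins$chrom[keep]
  chroms <- unique(m$bins$chrom)
  if (length(chroms) < 2)
    stop("contact enrichment needs >= 2 chromosomes", call. = FALSE)
  # observed contacts per chromosome pair (fully masked chromosomes keep a
  # zero row so pair indexing stays aligned)
  f <- factor(chrom, levels = chroms)
  k <- length(chroms)
  agg <- matrix(0, k, k, dimnames = list(chroms, chroms))
  if (nrow(v)) {
    rs <- rowsum(v, f)                # present chromosomes x bins
    tmp <- rowsum(t(rs), f)           # bins grouped again -> chrom x chrom
    agg[rownames(tmp), colnames(tmp)] <- tmp
  }
  diag(agg) <- 0                      # cis excluded
  trans_tot <- rowSums(agg)
  if (sum(trans_tot) == 0) stop("no trans contacts", call. = FALSE)
  pairs <- utils::combn(seq_along(chroms), 2)
  obs <- agg[t(pairs)]
  raw <- trans_tot[pairs[1, ]] * trans_tot[pairs[2, ]]
  exp_ <- raw * sum(obs) / sum(raw)
  ratio <- ifelse(obs > 0 & exp_ > 0, log2(obs / exp_), NA_real_)
  undef <- trans_tot[pairs[1, ]] == 0 | trans_tot[pairs[2, ]] == 0
  ratio[undef] <- NA_real_
  structure(data.frame(chrom_a = chroms[pairs[1, ]],
                       chrom_b = chroms[pairs[2, ]],
                       observed = obs, expected = exp_,
                       log2_ratio = ratio, stringsAsFactors = FALSE),
            class = c("pair_enrichment", "data.frame"))
}

#' Relative ChIP level of a repeat class
#'
#' Mean ChIP/input ratio over windows annotated with the repeat class,
#' divided by the mean over windows annotated `"unique"`.
#'
#' @param track data.frame with columns `ratio` (ChIP/input, >= 0) and
#'   `annotation` (repeat-class token or `"unique"`); windows are assumed
#'   non-overlapping.
#' @param repeat_class Annotation token of the repeat class.
#' @return A single numeric ratio.
#' @examples
#' track <- data.frame(ratio = c(2, 2, 0.5, 0.5),
#'                     annotation = c("LINE", "LINE", "unique", "unique"))
#' relative_chip_level(track, "LINE")  # 4
#' @export
relative_chip_level <- function(track, repeat_class) {
  stopifnot(is.data.frame(track),
            all(c("ratio", "annotation") %in% names(track)))
  if (any(track$ratio < 0)) stop("ChIP/input ratios must be >= 0",
                                 call. = FALSE)
  rep_w <- track$ratio[track$annotation == repeat_class]
  uniq_w <- track$ratio[track$annotation == "unique"]
  if (!length(rep_w)) stop("no windows annotated '", repeat_class, "'",
                           call. = FALSE)
  if (!length(uniq_w)) stop("no unique-sequence windows", call. = FALSE)
  mu <- mean(uniq_w)
  if (mu == 0) stop("unique-window mean is zero", call. = FALSE)
  mean(rep_w) / mu
}

#' Normalised expression of a multicopy (amplicon) gene family
#'
#' Mean read count across all copies, normalised by the total mRNA length of
#' the copies.
#'
#' @param read_counts Numeric vector of per-copy read counts.
#' @param mrna_lengths Numeric vector of per-copy mRNA lengths (bp, > 0).
#' @return `mean(read_counts) / sum(mrna_lengths)`.
#' @examples
#' amplicon_expression(c(10, 20, 30), c(1000, 1000, 1000))  # 20 / 3000
#' @export
amplicon_expression <- function(read_counts, mrna_lengths) {
  if (!length(read_counts)) stop("no copies given", call. = FALSE)
  stopifnot(length(read_counts) == length(mrna_lengths))
  if (any(mrna_lengths <= 0)) stop("mRNA lengths must be > 0", call. = FALSE)
  if (any(read_counts < 0)) stop("read counts must be >= 0", call. = FALSE)
  mean(read_counts) / sum(mrna_lengths)
}
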