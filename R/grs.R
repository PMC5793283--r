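GRS_CATEGORY_LEVELS <- c("0-5", "6-7", "8-10")

#' Round an imputed dosage to the closest hard genotype
#'
#' Dosages in `[0, 2]` are converted to allele counts by rounding to the
#' nearest integer. Exact half-way points (0.5, 1.5) — probability-zero for a
#' continuous dosage — round away from zero by convention. Values outside
#' `[0, 2]` by at most `tol` are clamped; anything farther is an error.
#'
#' @param dosage Numeric vector of dosages in `[0, 2]`.
#' @param tol Tolerance for out-of-range values (default `1e-8`).
#' @return Integer vector of allele counts in `{0, 1, 2}`.
#' @examples
#' round_dosage(c(0, 0.49, 0.5, 1.2, 2))
#' @export
round_dosage <- function(dosage, tol = 1e-8) {
  if (!is.numeric(dosage)) stop("dosage must be numeric", call. = FALSE)
  bad <- !is.na(dosage) & (dosage < -tol | dosage > 2 + tol)
  if (any(bad)) {
    stop("dosage outside [0, 2]: ",
         paste(format(utils::head(dosage[bad], 3)), collapse = ", "),
         call. = FALSE)
  }
  x <- pmin(pmax(dosage, 0), 2)
  # floor(x + 0.5) rounds half-way points up, i.e. away from zero on [0, 2]
  as.integer(floor(x + 0.5))
}

#' Compute the unweighted vitamin D genetic risk score
#'
#' The score is the plain sum of higher-25OHD allele counts over the 5-SNP
#' panel (theoretical range 0-10), reported with its fixed category
#' (0-5 reference, 6-7, 8-10) and the sensitivity variant that drops the GC
#' SNP rs2282679 (range 0-8).
#'
#' @param allele_counts Matrix or data frame (`n x 5`) of allele counts in
#'   `{0, 1, 2}`, or a single length-5 vector. Columns must be named by rsid
#'   when `snps` is supplied, and are reordered to the panel order.
#' @param snps The SNP panel used to validate column order and locate the GC
#'   SNP; defaults to [default_snp_panel()].
#' @return A data frame with columns `score`, `category` (factor),
#'   `score_no_gc`.
#' @examples
#' compute_grs(c(2, 1, 0, 1, 2))  # score 6, category "6-7", no-GC score 4
#' @export
compute_grs <- function(allele_counts, snps = default_snp_panel()) {
  rsids <- panel_rsids(snps)
  if (is.null(dim(allele_counts))) {
    if (length(allele_counts) != length(rsids)) {
      stop("expected ", length(rsids), " allele counts, got ",
           length(allele_counts), call. = FALSE)
    }
    allele_counts <- matrix(allele_counts, nrow = 1,
                            dimnames = list(NULL, rsids))
  }
  allele_counts <- as.matrix(allele_counts)
  if (ncol(allele_counts) != length(rsids)) {
    stop("expected ", length(rsids), " SNP columns, got ",
         ncol(allele_counts), call. = FALSE)
  }
  if (!is.null(colnames(allele_counts))) {
    missing <- setdiff(rsids, colnames(allele_counts))
    if (length(missing)) {
      stop("allele count columns do not match the SNP panel; missing: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    allele_counts <- allele_counts[, rsids, drop = FALSE]
  }
  ok <- allele_counts %in% c(0L, 1L, 2L)
  if (!all(ok)) {
    stop("allele counts must be 0, 1 or 2 (round dosages first); offending ",
         "value: ", format(allele_counts[which(!ok)[1]]), call. = FALSE)
  }
  storage.mode(allele_counts) <- "integer"
  gc_col <- which(rsids == "rs2282679")
  score <- as.integer(rowSums(allele_counts))
  score_no_gc <- if (length(gc_col) == 1L) {
    score - allele_counts[, gc_col]
  } else {
    score
  }
  data.frame(score = score,
             category = grs_category(score),
             score_no_gc = as.integer(score_no_gc))
}

#' Categorise scores with the fixed 0-5 / 6-7 / 8-10 cuts
#' @param score Integer vector of scores in `[0, 10]`.
#' @return Factor with levels `"0-5"`, `"6-7"`, `"8-10"` (reference first).
#' @export
grs_category <- function(score) {
  stopifnot(all(score >= 0 & score <= 10, na.rm = TRUE))
  cut(score, breaks = c(-0.5, 5.5, 7.5, 10.5),
      labels = GRS_CATEGORY_LEVELS)
}

#' Assign rank-based quintiles to a discrete score
#'
#' Discrete scores make exact 20% bins impossible, so the five groups are
#' chosen by exhaustive search over contiguous partitions of the observed
#' score values, minimising `sum(|bin size - n/5|)`; tied subjects always
#' share a quintile (a score value is never split), and ties between equally
#' good partitions resolve toward lower cut values. With fewer than five
#' distinct values the groups degenerate gracefully (one group per value)
#' and a warning is emitted.
#'
#' @param scores Integer (or integer-valued) vector, length >= 5.
#' @return Integer vector of quintile labels `1..5` (lower score = lower
#'   quintile); may use fewer than 5 labels when distinct values are scarce.
#' @export
assign_quintiles <- function(scores) {
  if (length(scores) < 5L) stop("need at least 5 subjects", call. = FALSE)
  vals <- sort(unique(scores))
  k <- length(vals)
  n <- length(scores)
  if (k == 1L) {
    warning("all scores identical; assigning a single quintile group")
    return(rep(1L, n))
  }
  counts <- tabulate(match(scores, vals), nbins = k)
  n_groups <- min(5L, k)
  if (k < 5L) {
    warning("only ", k, " distinct score values; using ", k, " groups")
    return(match(scores, vals))
  }
  # choose 4 cut positions (after value index) minimising sum |size - n/5|
  best <- NULL
  best_dev <- Inf
  csum <- cumsum(counts)
  for (cuts in utils::combn(k - 1L, 4L, simplify = FALSE)) {
    sizes <- diff(c(0, csum[c(cuts, k)]))
    dev <- sum(abs(sizes - n / 5))
    if (dev < best_dev - 1e-9) {  # strict improvement; first (lowest) cuts win ties
      best_dev <- dev
      best <- cuts
    }
  }
  grp <- findInterval(match(scores, vals), c(best + 0.5)) + 1L
  as.integer(grp)
}

#' Build the per-subject GRS table
#'
#' Convenience wrapper combining dosage rounding, score computation and
#' quintile assignment for a whole cohort.
#'
#' @param genotypes `n x 5` matrix/data frame of allele counts or dosages
#'   (dosages are rounded via [round_dosage()]).
#' @param snps The SNP panel.
#' @param id Optional subject identifiers (default row numbers).
#' @return Data frame `id, score, category, score_no_gc, quintile`.
#' @export
grs_table <- function(genotypes, snps = default_snp_panel(), id = NULL) {
  g <- as.matrix(genotypes)
  hard <- apply(g, 2, function(col) all(col == round(col)))
  if (!all(hard)) {
    g <- apply(g, 2, round_dosage)
  }
  res <- compute_grs(g, snps)
  res$quintile <- assign_quintiles(res$score)
  cbind(data.frame(id = if (is.null(id)) seq_len(nrow(res)) else id),
        res)
}
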