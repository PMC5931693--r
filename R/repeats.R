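# Transposon family classification.
#
# Individual repeat copies are first labelled ancestral (>= 1 bp overlap with
# ancestral elements or chain-blocks) or recent. A two-feature linear
# discriminant -- per-copy percent divergence from the family consensus, and
# the family-level bp proportion overlapping ancestral elements or
# chain-blocks broadcast to each copy -- is then fitted on the copy labels,
# and whole families are classified from their family-wise feature means.
# Copies of recent families that intersect chain-gaps are the
# lineage-specific insertion set.

#' Read a repeat annotation table
#'
#' Supports the RepeatMasker \code{.out} layout (3 header lines, whitespace
#' delimited, 1-based inclusive coordinates) and a simplified TSV dialect
#' with a header row \code{chrom start end family class pct_div} in 0-based
#' half-open coordinates.
#'
#' @param path File path.
#' @param format \code{"tsv"} or \code{"rmout"}.
#' @return data.frame (copy_id, chrom, start, end, family, repeat_class,
#'   pct_div), 0-based half-open.
#' @export
read_repeats <- function(path, format = c("tsv", "rmout")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "family", "class", "pct_div")
    if (!all(need %in% names(df)))
      stop("repeat TSV must have columns: ", paste(need, collapse = ", "))
    out <- data.frame(chrom = as.character(df$chrom), start = df$start,
                      end = df$end, family = as.character(df$family),
                      repeat_class = as.character(df$class),
                      pct_div = df$pct_div, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[-seq_len(min(3L, length(lines)))]
    lines <- lines[nzchar(trimws(lines))]
    toks <- strsplit(trimws(lines), "[ \t]+")
    get <- function(j) vapply(toks, `[`, "", j)
    out <- data.frame(chrom = get(5L),
                      start = as.numeric(get(6L)) - 1,  # 1-based -> half-open
                      end = as.numeric(get(7L)),
                      family = get(10L), repeat_class = get(11L),
                      pct_div = as.numeric(get(2L)), stringsAsFactors = FALSE)
  }
  if (any(out$pct_div < 0 | out$pct_div > 100))
    stop("pct_div outside [0, 100]")
  cbind(copy_id = seq_len(nrow(out)), out)
}

#' Per-family summary statistics
#'
#' @param repeats Repeat table as from \code{\link{read_repeats}}.
#' @param elements Ancestral element intervals.
#' @param blocks Chain-block intervals on the same genome.
#' @return data.frame (family, copy_count, total_bp, mean_pct_divergence,
#'   overlap_proportion), where overlap_proportion is the bp fraction of the
#'   family's copies intersecting elements-union-blocks. The family divergence
#'   mean is unweighted over copies.
#' @export
family_stats <- function(repeats, elements, blocks) {
  support <- ivl_union(elements, blocks)
  cov <- ivl_covered_bp(repeats, support)
  w <- repeats$end - repeats$start
  agg <- function(v, f) tapply(v, f, sum)
  fam <- sort(unique(repeats$family))
  data.frame(family = fam,
             copy_count = as.integer(table(repeats$family)[fam]),
             total_bp = as.numeric(agg(w, repeats$family)[fam]),
             mean_pct_divergence =
               as.numeric(tapply(repeats$pct_div, repeats$family, mean)[fam]),
             overlap_proportion =
               as.numeric((agg(cov, repeats$family) / agg(w, repeats$family))[fam]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Label individual repeat copies by ancestry
#'
#' A copy is ancestral iff it intersects (>= 1 bp) the union of ancestral
#' elements and chain-blocks; otherwise recent. Each copy also receives its
#' family's overlap proportion as the second classifier feature.
#'
#' @inheritParams family_stats
#' @return The repeat table with \code{ancestry_label} ("ancestral" or
#'   "recent") and \code{family_overlap} columns added.
#' @export
label_copies <- function(repeats, elements, blocks) {
  support <- ivl_union(elements, blocks)
  lab <- ifelse(ivl_hits(repeats, support), "ancestral", "recent")
  fs <- family_stats(repeats, elements, blocks)
  out <- repeats
  out$ancestry_label <- lab
  out$family_overlap <- fs$overlap_proportion[match(repeats$family, fs$family)]
  out
}

#' Fit the two-class linear discriminant family classifier
#'
#' Closed-form two-class LDA on features (pct_div, family_overlap): class
#' means, pooled within-class covariance, empirical priors, projection
#' weights proportional to the pooled-covariance inverse times the mean
#' difference, and the decision threshold they imply.
#'
#' @param copies Labelled copies from \code{\link{label_copies}}; both classes
#'   must be present. Training is on copy rows (the family-level overlap
#'   covariate is broadcast to copies).
#' @param ridge Optional non-negative ridge added to the diagonal of the
#'   pooled covariance. Required when the pooled covariance is singular
#'   (e.g. a feature constant within classes); the amount used is stored on
#'   the model.
#' @return A \code{repeat_lda} model with fields \code{means} (2 x 2 matrix,
#'   rows recent/ancestral), \code{cov} (pooled 2 x 2), \code{priors},
#'   \code{weights} and \code{threshold}: a point x is classified recent when
#'   \code{sum(weights * x) < threshold}.
#' @export
fit_family_classifier <- function(copies, ridge = NULL) {
  stopifnot(all(c("pct_div", "family_overlap", "ancestry_label") %in%
                  names(copies)))
  X <- as.matrix(copies[, c("pct_div", "family_overlap")])
  y <- copies$ancestry_label
  classes <- c("recent", "ancestral")
  if (!all(classes %in% y)) stop("both classes must be present for training")
  n <- table(factor(y, classes))
  mu <- t(vapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]),
                 numeric(2)))
  if (sum(abs(mu["recent", ] - mu["ancestral", ])) == 0)
    stop("identical class means: discriminant direction is undefined")
  S <- matrix(0, 2, 2)
  for (k in classes) {
    Xi <- X[y == k, , drop = FALSE]
    if (nrow(Xi) > 1) S <- S + stats::cov(Xi) * (nrow(Xi) - 1)
  }
  S <- S / (sum(n) - 2)
  if (!is.null(ridge)) {
    stopifnot(ridge >= 0)
    S <- S + diag(ridge, 2)
  }
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv) || !all(is.finite(Sinv)))
    stop("pooled covariance is singular; refit with a small ridge, ",
         "e.g. fit_family_classifier(copies, ridge = 1e-6)")
  priors <- as.numeric(n) / sum(n)
  names(priors) <- classes
  # w'x compared against threshold; w points from recent towards ancestral
  w <- drop(Sinv %*% (mu["ancestral", ] - mu["recent", ]))
  thr <- sum(w * (mu["ancestral", ] + mu["recent", ])) / 2 -
    log(priors["ancestral"] / priors["recent"])
  structure(list(means = mu, cov = S, priors = priors, weights = w,
                 threshold = unname(thr), ridge = ridge,
                 features = c("pct_div", "family_overlap")),
            class = "repeat_lda")
}

#' @export
print.repeat_lda <- function(x, ...) {
  cat("Two-class linear discriminant (recent vs ancestral repeat families)\n")
  cat("  priors: recent", signif(x$priors["recent"], 3),
      "/ ancestral", signif(x$priors["ancestral"], 3), "\n")
  cat("  weights (pct_div, family_overlap):",
      paste(signif(x$weights, 4), collapse = ", "),
      " threshold:", signif(x$threshold, 4), "\n")
  if (!is.null(x$ridge)) cat("  ridge:", x$ridge, "\n")
  invisible(x)
}

#' Predict the class of feature points under a fitted discriminant
#'
#' @param object A \code{repeat_lda} model.
#' @param newdata Matrix or data.frame with the two feature columns
#'   (pct_div / mean divergence first, overlap proportion second).
#' @param ... Unused.
#' @return Character vector, "recent" or "ancestral". Boundary points go to
#'   the class with the larger prior (ties to "ancestral").
#' @export
predict.repeat_lda <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  score <- drop(X %*% object$weights)
  out <- ifelse(score > object$threshold, "ancestral",
                ifelse(score < object$threshold, "recent",
                       names(which.max(object$priors))))
  unname(out)
}

#' Classify whole repeat families
#'
#' Families are classified from their family-wise feature means
#' (mean_pct_divergence, overlap_proportion).
#'
#' @param model A fitted \code{repeat_lda}.
#' @param stats Family table from \code{\link{family_stats}}.
#' @return Named character vector, family -> "recent"/"ancestral".
#' @export
classify_families <- function(model, stats) {
  cls <- predict(model,
                 stats[, c("mean_pct_divergence", "overlap_proportion")])
  stats::setNames(cls, stats$family)
}

#' Lineage-specific insertions
#'
#' Copies whose family is classified recent and which intersect (>= 1 bp) a
#' chain-gap are lineage-specific insertions; recent-family copies not
#' overlapping any gap are excluded (they stay in family statistics only).
#'
#' @param repeats Repeat table.
#' @param recent_families Character vector of family names classified recent.
#' @param gaps Chain-gap table from \code{\link{extract_features}} (uses the
#'   chrom/ref_start/ref_end columns) or any interval data.frame with
#'   chrom/start/end.
#' @return data.frame of insertion intervals (chrom, start, end, family).
#' @export
recent_insertions <- function(repeats, recent_families, gaps) {
  if (all(c("ref_start", "ref_end") %in% names(gaps)))
    gaps <- ivl(gaps$chrom, gaps$ref_start, gaps$ref_end)
  keep <- repeats$family %in% recent_families &
    ivl_hits(repeats, gaps)
  out <- repeats[keep, c("chrom", "start", "end", "family"), drop = FALSE]
  rownames(out) <- NULL
  out
}
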