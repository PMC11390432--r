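#' Select the counting slice for a PVS rating region
#'
#' The two standard rating regions are counted on anatomically defined
#' axial slices: the basal ganglia (BG) on the slice showing the anterior
#' commissure, and the centrum semiovale (CSO) on the slice 1 cm above the
#' uppermost slice of the lateral ventricles. With slice thickness `t` mm
#' the CSO slice is `ventricle_top + ceiling(10 / t)`.
#'
#' @param landmarks A list carrying landmark indices: `bg_slice_index`
#'   for BG, `ventricle_top_index` for CSO (a `phantom_truth` object works
#'   directly). For real data supply the indices measured by a reader.
#' @param region `"BG"` or `"CSO"`.
#' @param slice_thickness_mm Axial slice thickness in mm (default 2).
#' @param n_slices Optional volume depth; out-of-range selections are
#'   clamped into range with a warning.
#' @return Integer slice index (1-based).
#' @export
select_slice <- function(landmarks, region = c("BG", "CSO"),
                         slice_thickness_mm = 2, n_slices = NULL) {
  region <- match.arg(region)
  if (region == "BG") {
    idx <- landmarks$bg_slice_index
    if (is.null(idx)) stop("BG selection needs 'bg_slice_index' ",
                           "(anterior-commissure slice); supply it explicitly")
  } else {
    top <- landmarks$ventricle_top_index
    if (is.null(top)) stop("CSO selection needs 'ventricle_top_index'; ",
                           "supply it explicitly")
    idx <- top + as.integer(ceiling(10 / slice_thickness_mm))
  }
  if (!is.null(n_slices) && (idx < 1L || idx > n_slices)) {
    clamped <- min(max(idx, 1L), n_slices)
    warning("selected slice ", idx, " outside volume; clamped to ", clamped)
    idx <- clamped
  }
  as.integer(idx)
}

#' Count distinct PVS cross-sections on one axial slice
#'
#' Counts connected components of the binary mask restricted to one slice.
#' 8-connectivity is the default: a thin structure crossing the slice
#' obliquely whose pixels touch diagonally is one PVS, not two.
#'
#' @param mask 3D binary array (z = third axis) or a 2D binary matrix.
#' @param slice_index 1-based slice index (ignored for a 2D input).
#' @param connectivity 8 (default) or 4.
#' @param min_area Minimum component area in pixels; components smaller
#'   than this are ignored. Default 1 (filter off).
#' @return Integer component count.
#' @export
count_on_slice <- function(mask, slice_index = NULL, connectivity = 8,
                           min_area = 1) {
  stopifnot(connectivity %in% c(4, 8), min_area >= 1)
  if (length(dim(mask)) == 3L) {
    if (is.null(slice_index)) stop("slice_index required for a 3D mask")
    if (slice_index < 1L || slice_index > dim(mask)[3L]) {
      stop("slice_index ", slice_index, " out of range 1..", dim(mask)[3L])
    }
    sl <- mask[, , slice_index]
  } else {
    sl <- mask
  }
  lab <- label_cc(matrix(as.integer(sl != 0), nrow(sl), ncol(sl)),
                  as.integer(connectivity))
  k <- max(lab)
  if (k == 0L) return(0L)
  if (min_area > 1) {
    sizes <- tabulate(lab[lab > 0L], nbins = k)
    k <- sum(sizes >= min_area)
  }
  as.integer(k)
}

#' Spearman rank correlation for count data
#'
#' Tie-corrected (average-rank) Spearman correlation between two count
#' vectors, with a two-sided p-value by exact permutation of one vector for
#' `n <= 8` and by the t approximation
#' `t = rs * sqrt((n - 2) / (1 - rs^2))` on `n - 2` degrees of freedom
#' otherwise.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return A list of class `correlation_result` with `rs`, `p_value`, `n`.
#'   A constant input vector leaves `rs` undefined (`NA`) with a warning.
#' @export
spearman_counts <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant input vector: rank correlation undefined")
    return(structure(list(rs = NA_real_, p_value = NA_real_, n = n),
                     class = "correlation_result"))
  }
  rx <- rank(x)
  ry <- rank(y)
  rs <- stats::cor(rx, ry)
  if (n <= 8L) {
    obs <- abs(rs)
    perms <- permutations_of(n)
    cnt <- 0L
    for (i in seq_len(nrow(perms))) {
      if (abs(stats::cor(rx, ry[perms[i, ]])) >= obs - 1e-12) cnt <- cnt + 1L
    }
    p <- cnt / nrow(perms)
  } else {
    tstat <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(rs = rs, p_value = p, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rs = %.3f, p = %.4g, n = %d\n",
              x$rs, x$p_value, x$n))
  invisible(x)
}

# All permutations of 1..n as rows (n! x n matrix), iterative heap-free
# construction; used only for small n.
permutations_of <- function(n) {
  out <- matrix(1L, 1L, 1L)
  for (k in 2L:n) {
    prev <- out
    out <- matrix(0L, nrow(prev) * k, k)
    r <- 0L
    for (i in seq_len(nrow(prev))) {
      for (pos in seq_len(k)) {
        r <- r + 1L
        out[r, ] <- append(prev[i, ], k, after = pos - 1L)
      }
    }
  }
  out
}

#' Agreement between model-derived and rater PVS counts
#'
#' Computes, per region, the Spearman correlation of every model source
#' against every rater source and of raters against each other, mirroring
#' the count-agreement analysis a reader study reports.
#'
#' @param counts `data.frame` with columns `subject_id`, `region`, `count`,
#'   `source`; sources beginning with `"rater"` are treated as raters, all
#'   others as models.
#' @return `data.frame` with columns `region`, `source_a`, `source_b`,
#'   `kind` (`model_vs_rater` or `rater_vs_rater`), `rs`, `p_value`, `n`.
#'   Subjects missing from either source of a pair are excluded with a
#'   warning.
#' @export
agreement_report <- function(counts) {
  stopifnot(all(c("subject_id", "region", "count", "source") %in%
                  names(counts)))
  out <- list()
  for (reg in unique(counts$region)) {
    d <- counts[counts$region == reg, ]
    sources <- unique(d$source)
    raters <- sources[grepl("^rater", sources)]
    models <- setdiff(sources, raters)
    pairs <- list()
    for (m in models) for (r in raters) {
      pairs[[length(pairs) + 1L]] <- c(m, r, "model_vs_rater")
    }
    if (length(raters) >= 2L) {
      cmb <- utils::combn(raters, 2L)
      for (i in seq_len(ncol(cmb))) {
        pairs[[length(pairs) + 1L]] <- c(cmb[1L, i], cmb[2L, i],
                                         "rater_vs_rater")
      }
    }
    for (p in pairs) {
      a <- d[d$source == p[1L], ]
      b <- d[d$source == p[2L], ]
      common <- intersect(a$subject_id, b$subject_id)
      if (length(common) < length(unique(c(a$subject_id, b$subject_id)))) {
        warning("region ", reg, ", pair ", p[1L], " vs ", p[2L],
                ": subjects missing from one source were excluded")
      }
      cr <- spearman_counts(a$count[match(common, a$subject_id)],
                            b$count[match(common, b$subject_id)])
      out[[length(out) + 1L]] <- data.frame(
        region = reg, source_a = p[1L], source_b = p[2L], kind = p[3L],
        rs = cr$rs, p_value = cr$p_value, n = cr$n)
    }
  }
  do.call(rbind, out)
}
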