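# MAF partitioning and overlapping rare-variant window construction.
#
# Windows live in rare-variant *rank* space: rank r is the r-th rare variant
# in genomic order (0-based internally, half-open [start, end)).  Windows
# hold `window_size` rare variants and adjacent windows overlap by
# `window_size - step` variants, so their genomic length varies with local
# variant density and with the MAF threshold used to define rarity.

#' Split variants into rare and common by a MAF threshold
#'
#' Rarity is strict: a variant is rare iff `maf < threshold`, so a variant
#' sitting exactly on the cutoff is common.
#'
#' @param g a [genotype_matrix()].
#' @param threshold MAF cutoff in `(0, 0.5]`; conventional values are
#'   0.005, 0.01 and 0.05.
#' @return an object of class `maf_partition` with `threshold`, `rare_idx`
#'   and `common_idx` (1-based column indices into `g`).
#' @export
split_by_maf <- function(g, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 0.5)
    stop_winsig("threshold must be in (0, 0.5]", "winsig_bad_argument")
  rare <- which(g$maf < threshold)
  structure(
    list(threshold = threshold,
         rare_idx = rare,
         common_idx = setdiff(seq_along(g$maf), rare)),
    class = "maf_partition")
}

#' Build the overlapping sliding-window tiling over rare variants
#'
#' Window starts advance by `step` ranks: 0, `step`, `2*step`, ...  Each
#' window covers `window_size` rare variants except possibly a retained
#' terminal partial window ending at `n_rare`.  For `n_rare > window_size`
#' the number of windows is `ceiling(n_rare / step) - 1`; this is the
#' tiling that reproduces the published chromosome-3 window counts for all
#' three MAF thresholds.  Every rare variant belongs to at least one
#' window, and with the default half-overlap each interior variant belongs
#' to exactly two.
#'
#' @param n_rare number of rare variants to tile.
#' @param window_size variants per window (default 50).
#' @param step advance between adjacent window starts (default 25, i.e.
#'   half-overlapping windows).
#' @return an object of class `window_set`: a list with `windows` (a
#'   data.frame with 0-based half-open `start_rank`, `end_rank`), plus
#'   `window_size`, `step`, `n_rare`.
#' @export
build_windows <- function(n_rare, window_size = 50, step = 25) {
  n_rare <- assert_scalar_count(n_rare, "n_rare")
  window_size <- assert_scalar_count(window_size, "window_size")
  step <- assert_scalar_count(step, "step")
  if (step > window_size)
    stop_winsig("step must not exceed window_size", "winsig_bad_argument")
  if (n_rare <= window_size) {
    starts <- 0
  } else {
    k <- ceiling(n_rare / step) - 1
    starts <- step * (seq_len(k) - 1)
  }
  ends <- pmin(starts + window_size, n_rare)
  structure(
    list(windows = data.frame(window_id = seq_along(starts),
                              start_rank = starts, end_rank = ends),
         window_size = window_size, step = step, n_rare = n_rare),
    class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf(
    "<window_set> %d windows of %d rare variants (step %d) over %s ranks\n",
    n_windows(x), x$window_size, x$step, format(x$n_rare, big.mark = ",")))
  invisible(x)
}

#' Number of windows in a window set
#' @param ws a [build_windows()] result.
#' @return integer count.
#' @export
n_windows <- function(ws) nrow(ws$windows)

#' Column indices of a window's variants in the parent genotype matrix
#' @param ws a `window_set`.
#' @param part the `maf_partition` the windows were built over.
#' @param w window id.
#' @return integer vector of genotype-matrix column indices.
#' @export
window_variant_idx <- function(ws, part, w) {
  row <- ws$windows[w, ]
  part$rare_idx[(row$start_rank + 1):row$end_rank]
}

#' Tabulate windows with genomic spans as a BED-like table
#'
#' @param ws a `window_set` built over the rare variants of `part`.
#' @param g the parent [genotype_matrix()].
#' @param part the [split_by_maf()] partition used to build `ws`.
#' @return data.frame with columns `chrom`, `start0` (0-based), `end`
#'   (1-based inclusive end, i.e. BED-style half-open pair), `window_id`,
#'   `n_variants`, `start_rank`.
#' @export
window_table <- function(ws, g, part) {
  if (length(part$rare_idx) != ws$n_rare)
    stop_winsig("window set does not match the partition's rare count",
                "winsig_bad_argument")
  first <- part$rare_idx[ws$windows$start_rank + 1]
  last <- part$rare_idx[ws$windows$end_rank]
  data.frame(chrom = g$chrom,
             start0 = g$positions[first] - 1,
             end = g$positions[last],
             window_id = ws$windows$window_id,
             n_variants = ws$windows$end_rank - ws$windows$start_rank,
             start_rank = ws$windows$start_rank)
}

#' Write the window table as TSV
#' @param tab result of [window_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_window_table <- function(tab, path) {
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}
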