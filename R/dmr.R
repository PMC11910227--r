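#' Differentially methylated regions by sign-flip permutation
#'
#' A bump-hunting style region finder on the per-pair beta differences.
#' Probes are first grouped into clusters (same chromosome, inter-probe gap
#' at most `max_gap_bp`). Within a cluster, a candidate region is a maximal
#' run of consecutive probes whose mean paired beta change has the same sign
#' and absolute value at least `delta_cut`; runs shorter than `min_probes`
#' are discarded. The region statistic is the area, the sum of absolute mean
#' changes over the run. The null distribution of the genome-wide maximum
#' area is obtained by flipping the sign of each participant's within-pair
#' difference: all `2^pairs` sign assignments are enumerated when there are
#' at most 10 pairs (giving an exact permutation p with resolution
#' `1/2^pairs`), otherwise `n_perm` random flips are drawn. Each region's
#' p-value is the fraction of null maximum areas at least as large as its
#' area, then Benjamini-Hochberg adjusted across regions.
#'
#' @inheritParams paired_dmp
#' @param annotation Probe annotation with `probe_id`, `chrom`, `pos`
#'   (1-based), sorted by chromosome and position.
#' @param max_gap_bp Maximum gap between neighbouring probes in a cluster.
#' @param min_probes Minimum number of probes in a reported region.
#' @param delta_cut Minimum absolute mean beta change per probe.
#' @param n_perm Number of random sign flips when enumeration is infeasible.
#' @param seed Optional seed for the random flips.
#' @return Tibble with `chrom`, `start`, `end` (1-based, closed), `n_probes`,
#'   `area`, `mean_delta`, `p_value`, `p_adjusted`.
#' @export
find_dmrs <- function(beta, design, annotation,
                      max_gap_bp = 500, min_probes = 3, delta_cut = 0.1,
                      n_perm = 1000, seed = NULL) {
  design <- ensure_design(design)
  if (n_perm < 100) warn("n_perm < 100 gives a very coarse permutation null")
  b <- wide_to_matrix(beta, "probe_id")
  ann <- annotation[match(rownames(b), annotation$probe_id), ]
  if (anyNA(ann$probe_id)) abort("annotation does not cover every probe")
  ord <- order(ann$chrom, ann$pos)
  if (!identical(ord, seq_len(nrow(ann)))) {
    abort("annotation (and beta) must be sorted by (chrom, pos)")
  }

  pm <- paired_matrices(b, design)
  d <- pm$on - pm$base # probe x pairs
  n_pairs <- ncol(d)

  # cluster ids: same chrom, gap <= max_gap_bp
  new_cluster <- c(TRUE, ann$chrom[-1] != ann$chrom[-nrow(ann)] |
                     diff(ann$pos) > max_gap_bp)
  cluster <- cumsum(new_cluster)

  obs <- candidate_runs(rowMeans(d), cluster, delta_cut, min_probes)
  if (nrow(obs) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_probes = integer(), area = double(), mean_delta = double(),
                  p_value = double(), p_adjusted = double()))
  }

  flips <- if (n_pairs <= 10) {
    sign_matrix(n_pairs)
  } else {
    if (!is.null(seed)) set.seed(seed)
    matrix(sample(c(-1, 1), n_pairs * n_perm, replace = TRUE), nrow = n_pairs)
  }
  null_max <- apply(flips, 2, function(s) {
    runs <- candidate_runs(drop(d %*% s) / n_pairs, cluster, delta_cut, min_probes)
    if (nrow(runs) == 0) 0 else max(runs$area)
  })

  p <- vapply(obs$area, function(a) mean(null_max >= a), double(1))
  tibble(chrom = ann$chrom[obs$from],
         start = ann$pos[obs$from],
         end = ann$pos[obs$to],
         n_probes = obs$to - obs$from + 1L,
         area = obs$area,
         mean_delta = obs$mean_delta,
         p_value = p,
         p_adjusted = p.adjust(p, method = "BH"))
}

# Maximal same-sign runs with |mean delta| >= cut inside clusters.
candidate_runs <- function(m, cluster, delta_cut, min_probes) {
  ok <- abs(m) >= delta_cut
  sgn <- sign(m) * ok
  n <- length(m)
  boundary <- c(TRUE, cluster[-1] != cluster[-n] | sgn[-1] != sgn[-n])
  rid <- cumsum(boundary)
  first <- match(seq_len(max(rid)), rid)
  runs <- tibble(from = first,
                 len = tabulate(rid),
                 sgn = sgn[first])
  runs$to <- runs$from + runs$len - 1L
  runs <- runs[runs$sgn != 0 & runs$len >= min_probes, , drop = FALSE]
  if (nrow(runs) == 0) {
    return(tibble(from = integer(), to = integer(), area = double(),
                  mean_delta = double()))
  }
  area <- vapply(seq_len(nrow(runs)),
                 function(i) sum(abs(m[runs$from[i]:runs$to[i]])), double(1))
  tibble(from = runs$from, to = runs$to, area = area,
         mean_delta = area / runs$len * sign(runs$sgn))
}

# All 2^n sign vectors as an n x 2^n matrix.
sign_matrix <- function(n) {
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  t(unname(grid))
}

#' Write regions as a BED file
#'
#' Region tables in this package use 1-based closed coordinates (the array
#' manifest convention); BED is 0-based half-open, so the start is shifted
#' down by one at this writer boundary.
#'
#' @param dmrs Region tibble from [find_dmrs()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- tibble(chrom = dmrs$chrom,
                start = dmrs$start - 1L,
                end = dmrs$end,
                name = sprintf("dmr_%d", seq_len(nrow(dmrs))),
                score = round(pmin(1000, -10 * log10(pmax(dmrs$p_adjusted, 1e-100)))),
                strand = ".")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
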