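# Spatially-correlated p-value region calling.
#
# Stages mirror the classical combined-probes construction: (1) estimate
# the autocorrelation of probit-transformed p-values as a function of
# genomic distance; (2) smooth each probe's p-value with its neighbours via
# the Stouffer-Liptak-Kechris combination, whose variance term accounts for
# the estimated correlation; (3) call candidate regions as runs of smoothed
# p below a seed threshold, merging across gaps up to the window size and
# never across chromosomes; (4) combine the RAW p-values within each region
# (again correlation-adjusted) and apply a Sidak correction for the number
# of effective windows. Coordinates are 0-based half-open internally; a
# single-probe region spans [pos, pos+1).

#' Build a sorted p-value track
#'
#' @param chrom chromosome labels.
#' @param pos base-pair positions (1-based probe coordinates).
#' @param p raw p-values in (0, 1]; zeros are clipped with a warning.
#' @param probe_id optional probe identifiers.
#' @return data.frame sorted by (chrom, pos), class \code{pval_track}.
#' @export
pval_track <- function(chrom, pos, p, probe_id = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  if (any(p == 0, na.rm = TRUE)) {
    warning("p-values of 0 clipped to 1e-300")
    p <- pmax(p, 1e-300)
  }
  d <- data.frame(chrom = as.character(chrom), pos = as.integer(pos), p = p,
                  probe_id = probe_id %||% paste0("probe_", seq_along(p)),
                  stringsAsFactors = FALSE)
  d <- d[order(d$chrom, d$pos), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("pval_track", "data.frame")
  d
}

#' Estimate the distance-binned autocorrelation of a p-value track
#'
#' For each distance bin (left-open, right-closed: (0,bin], (bin,2*bin],
#' ... up to \code{max_dist}), the Pearson correlation of
#' probit-transformed p-values over all same-chromosome probe pairs at
#' that separation, clipped to [0, 1).
#'
#' @param track a \code{\link{pval_track}}.
#' @param max_dist maximum pair distance in bp (default 500, the sliding
#'   window size).
#' @param bin_size bin width in bp (default 50).
#' @return data.frame with \code{dist_hi} (bin upper edge), \code{acf}
#'   (clipped correlation), \code{n_pairs}.
#' @export
acf_estimate <- function(track, max_dist = 500, bin_size = 50) {
  ## upper-tail quantile: numerically exact even for p near 1e-300
  z <- stats::qnorm(clip_p(track$p), lower.tail = FALSE)
  n_bins <- ceiling(max_dist / bin_size)
  sums <- matrix(0, n_bins, 5)  # sum x, sum y, sum xy, sum x2, sum y2
  counts <- integer(n_bins)
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    if (length(idx) < 2) next
    pos <- track$pos[idx]; zc <- z[idx]
    for (i in seq_along(idx)) {
      j <- i + 1
      while (j <= length(idx) && pos[j] - pos[i] <= max_dist) {
        d <- pos[j] - pos[i]
        if (d > 0) {
          b <- ceiling(d / bin_size)
          counts[b] <- counts[b] + 1L
          sums[b, ] <- sums[b, ] + c(zc[i], zc[j], zc[i] * zc[j],
                                     zc[i]^2, zc[j]^2)
        }
        j <- j + 1
      }
    }
  }
  acf <- vapply(seq_len(n_bins), function(b) {
    n <- counts[b]
    if (n < 2) return(0)
    sx <- sums[b, 1]; sy <- sums[b, 2]
    cov <- sums[b, 3] / n - (sx / n) * (sy / n)
    vx <- sums[b, 4] / n - (sx / n)^2
    vy <- sums[b, 5] / n - (sy / n)^2
    if (vx <= 0 || vy <= 0) return(0)
    cov / sqrt(vx * vy)
  }, 0)
  if (all(counts == 0)) warning("no probe pairs in any distance bin; flat zero ACF")
  data.frame(dist_hi = bin_size * seq_len(n_bins),
             acf = pmin(pmax(acf, 0), 1 - 1e-9),
             n_pairs = counts)
}

# Look up the correlation for a vector of distances (0 beyond max).
.acf_at <- function(acf_tab, dist) {
  bin_size <- acf_tab$dist_hi[1]
  b <- ceiling(dist / bin_size)
  out <- numeric(length(dist))
  ok <- b >= 1 & b <= nrow(acf_tab)
  out[ok] <- acf_tab$acf[b[ok]]
  out
}

# Stouffer-Liptak combination of p-values with pairwise correlations from
# the ACF table: z_comb = sum(z_i) / sqrt(k + 2 * sum_{i<j} rho(d_ij)).
.slk_combine <- function(p, pos, acf_tab) {
  k <- length(p)
  z <- stats::qnorm(clip_p(p), lower.tail = FALSE)
  if (k == 1) return(clip_p(p))
  rho_sum <- 0
  for (i in seq_len(k - 1)) {
    rho_sum <- rho_sum + sum(.acf_at(acf_tab, pos[(i + 1):k] - pos[i]))
  }
  denom <- sqrt(k + 2 * rho_sum)
  stats::pnorm(sum(z) / denom, lower.tail = FALSE)
}

#' Smooth a p-value track by correlation-adjusted local combination
#'
#' Each probe's p-value is replaced by the Stouffer-Liptak-Kechris
#' combination of all probes within \code{window} bp on the same
#' chromosome (itself included). An isolated probe keeps its raw p; with
#' perfect correlation among k identical p-values the combination returns
#' the raw p unchanged (the denominator becomes k).
#'
#' @param track a \code{\link{pval_track}}.
#' @param acf ACF table from \code{\link{acf_estimate}}.
#' @param window half-window in bp (default 500).
#' @return the track with an added \code{p_smooth} column.
#' @export
slk_smooth <- function(track, acf, window = 500) {
  p_smooth <- numeric(nrow(track))
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    pos <- track$pos[idx]; p <- track$p[idx]
    lo <- 1; hi <- 1
    for (i in seq_along(idx)) {
      while (pos[i] - pos[lo] > window) lo <- lo + 1
      while (hi < length(idx) && pos[hi + 1] - pos[i] <= window) hi <- hi + 1
      sel <- lo:hi
      p_smooth[idx[i]] <- .slk_combine(p[sel], pos[sel], acf)
    }
  }
  track$p_smooth <- p_smooth
  track
}

#' Find candidate regions of low smoothed p-values
#'
#' Maximal runs of probes with smoothed p below \code{p_threshold}, merged
#' when consecutive qualifying probes are at most \code{max_gap} bp apart,
#' never spanning chromosomes. Output coordinates are 0-based half-open;
#' a single-probe region spans [pos, pos+1).
#'
#' @param track smoothed track from \code{\link{slk_smooth}}.
#' @param p_threshold seed threshold (default 1e-4).
#' @param max_gap merge gap in bp (default 500).
#' @return data.frame of candidate regions (chrom, start, end, n_probes,
#'   probe index range).
#' @export
find_regions <- function(track, p_threshold = 1e-4, max_gap = 500) {
  stopifnot(!is.null(track$p_smooth))
  hits <- which(track$p_smooth < p_threshold)
  if (length(hits) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0)))
  new_region <- c(TRUE,
                  diff(track$pos[hits]) > max_gap |
                    track$chrom[hits][-1] != track$chrom[hits][-length(hits)])
  grp <- cumsum(new_region)
  out <- do.call(rbind, lapply(split(hits, grp), function(ix) {
    data.frame(chrom = track$chrom[ix[1]],
               start = track$pos[ix[1]],             # half-open [pos, pos+1)
               end = track$pos[ix[length(ix)]] + 1L,
               n_probes = length(ix),
               idx_lo = ix[1], idx_hi = ix[length(ix)],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Correlation-adjusted combined p-value for a region
#'
#' Stouffer-Liptak combination of the RAW p-values of the probes inside
#' the region, using the estimated ACF.
#'
#' @param p raw p-values inside the region.
#' @param pos their positions.
#' @param acf ACF table.
#' @return combined p-value.
#' @export
region_p <- function(p, pos, acf) {
  if (length(p) == 0) stop("region is empty")
  .slk_combine(p, pos, acf)
}

#' Sidak correction for a region p-value
#'
#' \code{1 - (1 - p)^(total_covered_bp / region_bp)}: the exponent is the
#' number of effective windows of the region's width in the covered
#' genome.
#'
#' @param p_region combined region p-value.
#' @param region_bp region width in bp (> 0).
#' @param total_covered_bp total probe-covered footprint in bp.
#' @return corrected p-value in (0, 1].
#' @export
sidak_correct <- function(p_region, region_bp, total_covered_bp) {
  if (region_bp <= 0) stop("region_bp must be positive")
  k <- total_covered_bp / region_bp
  ## log-space so tiny region p-values do not underflow to 0
  -expm1(k * log1p(-clip_p(p_region)))
}

#' Full spatially-correlated region calling pipeline
#'
#' @param track a \code{\link{pval_track}}.
#' @param p_threshold seed threshold for candidate probes (default 1e-4).
#' @param window window/merge-gap size in bp (default 500).
#' @param bin_size ACF bin width.
#' @return data.frame of region calls: chrom, start, end (0-based
#'   half-open), n_probes, p_region, p_sidak; attribute
#'   \code{total_covered_bp}.
#' @export
call_dmrs <- function(track, p_threshold = 1e-4, window = 500,
                      bin_size = 50) {
  acf <- acf_estimate(track, max_dist = window, bin_size = bin_size)
  sm <- slk_smooth(track, acf, window = window)
  regions <- find_regions(sm, p_threshold = p_threshold, max_gap = window)
  ## covered footprint: per chromosome, one window's width per probe capped
  ## by the observed span
  covered <- sum(vapply(split(sm$pos, sm$chrom), function(pos) {
    min(max(pos) - min(pos) + window, length(pos) * window)
  }, 0))
  if (nrow(regions) == 0) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      p_region = numeric(0), p_sidak = numeric(0))
    attr(out, "total_covered_bp") <- covered
    return(out)
  }
  regions$p_region <- vapply(seq_len(nrow(regions)), function(i) {
    ix <- regions$idx_lo[i]:regions$idx_hi[i]
    region_p(sm$p[ix], sm$pos[ix], acf)
  }, 0)
  regions$p_sidak <- vapply(seq_len(nrow(regions)), function(i)
    sidak_correct(regions$p_region[i],
                  regions$end[i] - regions$start[i], covered), 0)
  out <- regions[, c("chrom", "start", "end", "n_probes",
                     "p_region", "p_sidak")]
  attr(out, "total_covered_bp") <- covered
  out
}
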