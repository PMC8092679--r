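# ChIP-seq-style coverage-profile ingestion and normalization, and RMSD
# grid fitting of SBM binding profiles over (sigma, omega).

new_coverage_profile <- function(pos, value, fragment_size = NA_real_,
                                 normalized = FALSE) {
  o <- order(pos)
  out <- data.frame(pos = as.numeric(pos[o]), value = as.numeric(value[o]))
  # merge duplicated positions by summing
  if (anyDuplicated(out$pos)) {
    agg <- aggregate(value ~ pos, data = out, FUN = sum)
    out <- agg[order(agg$pos), ]
    rownames(out) <- NULL
  }
  attr(out, "fragment_size") <- fragment_size
  attr(out, "normalized") <- normalized
  class(out) <- c("coverage_profile", "data.frame")
  out
}

#' Read a coverage profile
#'
#' Reads a position/value profile from a two-column TSV (point positions
#' in bp) or a standard 4-column bedGraph.  bedGraph intervals are 0-based
#' half-open; each interval's value is assigned to its center position
#' `(start + end) / 2`.  Duplicate positions are merged by summing.
#'
#' @param path file path.
#' @param format `"tsv"` or `"bedGraph"` (the latter requires the
#'   rtracklayer package).
#' @param fragment_size optional mean DNA fragment size (bp), stored as
#'   metadata.
#' @return A `coverage_profile` data frame with columns `pos`, `value`.
#' @export
read_coverage <- function(path, format = c("tsv", "bedGraph"),
                          fragment_size = NA_real_) {
  format <- match.arg(format)
  if (format == "tsv") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    if (length(lines) == 0) stop("empty coverage file: ", path)
    fields <- strsplit(lines, "[\t ]+")
    bad_n <- which(lengths(fields) < 2)
    if (length(bad_n))
      stop("line ", bad_n[1], ": expected two fields (position, value)")
    pos <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1)))
    val <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
    bad <- which(is.na(pos) | is.na(val))
    if (length(bad))
      stop("line ", bad[1], ": non-numeric position or value")
    new_coverage_profile(pos, val, fragment_size)
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading bedGraph requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "bedGraph")
    df <- as.data.frame(gr)
    if (nrow(df) == 0) stop("empty coverage file: ", path)
    # GRanges start is 1-based; recover the 0-based half-open interval
    start0 <- df$start - 1
    end0 <- df$end
    o <- order(as.character(df$seqnames), start0)
    if (any(diff(o) != 1) && is.unsorted(start0))
      df <- df[o, , drop = FALSE]
    ov <- which(head(end0[o], -1) > tail(start0[o], -1) &
                  head(as.character(df$seqnames)[o], -1) ==
                  tail(as.character(df$seqnames)[o], -1))
    if (length(ov))
      stop("overlapping bedGraph intervals near record ", ov[1])
    new_coverage_profile((start0 + end0) / 2, df$score, fragment_size)
  }
}

#' Background-subtract and max-normalize a coverage profile
#'
#' `value' = max(0, value - background) / max(value - background)`:
#' background-subtracted values are clipped at zero and the profile is set
#' to 1 at its maximum.
#'
#' @param cp a `coverage_profile`.
#' @param background scalar background level, or a length-2 window
#'   `c(lo, hi)` in bp over which the mean value estimates the background.
#' @return The normalized `coverage_profile`.
#' @export
normalize_profile <- function(cp, background = 0) {
  if (length(background) == 2) {
    inw <- cp$pos >= background[1] & cp$pos <= background[2]
    if (!any(inw)) stop("background window contains no positions")
    background <- mean(cp$value[inw])
  }
  stopifnot(background >= 0)
  v <- pmax(0, cp$value - background)
  m <- max(v)
  if (m <= 0) stop("profile is all zero after background subtraction")
  out <- new_coverage_profile(cp$pos, v / m,
                              attr(cp, "fragment_size"), normalized = TRUE)
  attr(out, "background") <- background
  out
}

#' Assign reads to fragment centers
#'
#' Each read contributes one count at its fragment center: plus-strand
#' reads at `start + fragment_size/2`, minus-strand reads at
#' `start - fragment_size/2`.  Total counts are conserved.
#'
#' @param starts read start positions (bp).
#' @param fragment_size mean DNA fragment size (bp, positive).
#' @param strand optional character vector (`"+"`/`"-"`); `NULL` treats
#'   all reads as plus-strand.
#' @return A `coverage_profile` of counts per center position.
#' @export
fragment_center_assign <- function(starts, fragment_size, strand = NULL) {
  stopifnot(fragment_size > 0)
  shift <- if (is.null(strand)) fragment_size / 2
           else ifelse(strand == "-", -fragment_size / 2, fragment_size / 2)
  centers <- starts + shift
  tab <- table(centers)
  new_coverage_profile(as.numeric(names(tab)), as.numeric(tab),
                       fragment_size)
}

#' RMSD between a model binding profile and coverage data
#'
#' The model is linearly interpolated onto the data positions inside the
#' fit window and the root-mean-square deviation is returned.  No
#' amplitude rescaling is applied: both curves are expected on the common
#' max-normalized `[0, 1]` scale.  The default window `[1.5 kb, 9 kb]`
#' avoids the parS region and reproducible promoter/roadblock distortions.
#'
#' @param model a [binding_profile()] (columns `s_bp`, `B`).
#' @param data a normalized `coverage_profile`.
#' @param window fit window `c(s_min, s_max)` in bp; at least 10 data
#'   points must fall inside.
#' @return RMSD (same units as the profiles).
#' @export
profile_rmsd <- function(model, data, window = c(1500, 9000)) {
  sel <- data$pos >= window[1] & data$pos <= window[2]
  if (sum(sel) < 10)
    stop("fewer than 10 data points in the fit window")
  m <- approx(model$s_bp, model$B, xout = data$pos[sel], rule = 1)$y
  if (anyNA(m))
    stop("model profile does not cover the fit window")
  sqrt(mean((m - data$value[sel])^2))
}

#' Model binding profiles over a (sigma, omega) grid
#'
#' Precomputes `B(s)` for every combination of sigma level (one set of
#' distance samples each) and cluster width omega.  Useful to amortize the
#' model computation across repeated fits of the same grid.
#'
#' @param samples_by_sigma named list of [distance_samples()] objects (one
#'   per sigma; names are the sigma labels).
#' @param omega_grid cluster FWHM values (nm).
#' @param kind cluster kind, see [cluster_model()].
#' @param ... further arguments to [cluster_model()].
#' @return Nested list `[[sigma]][[omega]]` of `binding_profile`s, with
#'   attributes `sigma_labels` and `omega_grid`.
#' @export
model_binding_profiles <- function(samples_by_sigma, omega_grid,
                                   kind = "leaky", ...) {
  out <- lapply(samples_by_sigma, function(ds)
    lapply(omega_grid, function(w)
      binding_profile(ds, cluster_model(kind, omega = w, ...))))
  attr(out, "sigma_labels") <- names(samples_by_sigma)
  attr(out, "omega_grid") <- omega_grid
  out
}

#' Grid fit of the SBM against a coverage profile
#'
#' Computes the RMSD between the model binding profile and the data for
#' every (sigma, omega) cell and reports the best cell.  Ties are broken
#' toward smaller omega, then larger |sigma|.
#'
#' @inheritParams model_binding_profiles
#' @param data a normalized `coverage_profile` with positions relative to
#'   the parS-edge origin.
#' @param window fit window in bp, see [profile_rmsd()].
#' @param model_profiles optional precomputed output of
#'   [model_binding_profiles()] (overrides `samples_by_sigma`,
#'   `omega_grid`, `kind`).
#' @return Object of class `sbm_fit`: `rmsd` matrix (sigma x omega),
#'   `best` (list with `sigma`, `omega`, `rmsd`), `window`, grids.
#' @export
grid_fit <- function(samples_by_sigma = NULL, data, omega_grid,
                     kind = "leaky", window = c(1500, 9000),
                     model_profiles = NULL, ...) {
  if (is.null(model_profiles))
    model_profiles <- model_binding_profiles(samples_by_sigma, omega_grid,
                                             kind, ...)
  sig_lab <- attr(model_profiles, "sigma_labels")
  omega_grid <- attr(model_profiles, "omega_grid")
  n_s <- length(model_profiles)
  n_w <- length(omega_grid)
  rmsd <- matrix(NA_real_, n_s, n_w,
                 dimnames = list(sigma = sig_lab, omega = omega_grid))
  for (i in seq_len(n_s))
    for (j in seq_len(n_w))
      rmsd[i, j] <- profile_rmsd(model_profiles[[i]][[j]], data, window)
  sig_num <- suppressWarnings(as.numeric(sig_lab))
  if (anyNA(sig_num)) sig_num <- seq_len(n_s)
  cells <- expand.grid(i = seq_len(n_s), j = seq_len(n_w))
  cells$rmsd <- rmsd[cbind(cells$i, cells$j)]
  cells$omega <- omega_grid[cells$j]
  cells$abs_sigma <- abs(sig_num)[cells$i]
  ord <- order(cells$rmsd, cells$omega, -cells$abs_sigma)
  b <- cells[ord[1], ]
  structure(list(rmsd = rmsd,
                 best = list(sigma = sig_lab[b$i], omega = b$omega,
                             rmsd = b$rmsd, i = b$i, j = b$j),
                 window = window, omega_grid = omega_grid,
                 sigma_labels = sig_lab),
            class = "sbm_fit")
}

#' @export
print.sbm_fit <- function(x, ...) {
  cat(sprintf("SBM grid fit: %d sigma x %d omega cells, window [%g, %g] bp\n",
              nrow(x$rmsd), ncol(x$rmsd), x$window[1], x$window[2]))
  cat(sprintf("  best: sigma = %s, omega = %g nm (RMSD %.4g)\n",
              x$best$sigma, x$best$omega, x$best$rmsd))
  invisible(x)
}
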