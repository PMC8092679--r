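# Plain-text persistence of conformational ensembles.  One TSV holds the
# full provenance (run, sigma level, frame, sweep metadata) plus vertex
# coordinates; an XYZ exporter is provided for molecular viewers.

#' Write a conformational ensemble to a plain-text trajectory file
#'
#' Serializes frames as a TSV with columns `level`, `run`, `frame`,
#' `vertex`, `x`, `y`, `z` (nm), preceded by commented header lines
#' carrying `n_bp`, `Lk0`, the per-level sigma/Lk table and the master
#' seed, so a written file round-trips through [read_trajectory()].
#'
#' @param ensemble a `conformation_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# parbsbm trajectory v1"), con)
  writeLines(sprintf("# n_bp=%d Lk0=%g l=%g n_runs=%d seed=%d",
                     ensemble$n_bp, ensemble$Lk0, ensemble$l,
                     ensemble$n_runs, ensemble$seed), con)
  writeLines(sprintf("# level=%d sigma=%.10g Lk=%g",
                     ensemble$levels$level, ensemble$levels$sigma,
                     ensemble$levels$Lk), con)
  writeLines("level\trun\tframe\tvertex\tx\ty\tz", con)
  for (t in seq_along(ensemble$frames))
    for (r in seq_along(ensemble$frames[[t]])) {
      fr <- ensemble$frames[[t]][[r]]
      for (f in seq_along(fr)) {
        V <- fr[[f]]
        n <- nrow(V)
        writeLines(sprintf("%d\t%d\t%d\t%d\t%.8g\t%.8g\t%.8g",
                           t, r, f, seq_len(n), V[, 1], V[, 2], V[, 3]),
                   con)
      }
    }
  invisible(path)
}

#' Read a plain-text trajectory file
#'
#' @param path file written by [write_trajectory()].
#' @return A `conformation_ensemble` (frames, levels and chain metadata;
#'   per-frame writhe and diagnostics are not persisted).
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  meta <- regmatches(hdr[2], gregexpr("[a-zA-Z_0-9]+=[-0-9.e+]+", hdr[2]))[[1]]
  kv <- strsplit(meta, "=")
  vals <- setNames(as.numeric(vapply(kv, `[`, "", 2)),
                   vapply(kv, `[`, "", 1))
  lev_lines <- hdr[startsWith(hdr, "# level=")]
  lev <- do.call(rbind, lapply(lev_lines, function(ln) {
    m <- regmatches(ln, gregexpr("[a-zA-Z_0-9]+=[-0-9.e+]+", ln))[[1]]
    p <- strsplit(m, "=")
    setNames(as.numeric(vapply(p, `[`, "", 2)), vapply(p, `[`, "", 1))
  }))
  body <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                     sep = "\t")
  n_lev <- nrow(lev)
  n_runs <- as.integer(vals["n_runs"])
  frames <- rep(list(vector("list", n_runs)), n_lev)
  for (t in seq_len(n_lev))
    for (r in seq_len(n_runs)) {
      sub <- body[body$level == t & body$run == r, ]
      if (nrow(sub) == 0) next
      frames[[t]][[r]] <- lapply(split(sub, sub$frame), function(ff)
        unname(as.matrix(ff[order(ff$vertex), c("x", "y", "z")])))
      names(frames[[t]][[r]]) <- NULL
    }
  structure(list(levels = data.frame(level = seq_len(n_lev),
                                     sigma_nominal = lev[, "sigma"],
                                     sigma = lev[, "sigma"],
                                     Lk = lev[, "Lk"]),
                 frames = frames, wr = NULL, acceptance = NULL,
                 n_bp = as.integer(vals["n_bp"]),
                 n_cylinders = as.integer(vals["n_bp"] / 30),
                 Lk0 = vals["Lk0"], l = vals["l"],
                 n_runs = n_runs, seed = as.integer(vals["seed"])),
            class = "conformation_ensemble")
}

#' Export conformations as XYZ frames
#'
#' Plain multi-frame XYZ (one block per conformation, element tag `C`) for
#' visualization in standard molecular viewers.
#'
#' @param frames list of N x 3 vertex matrices (nm).
#' @param path output file.
#' @param comment per-frame comment prefix.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, comment = "sRLC frame") {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    V <- frames[[f]]
    writeLines(as.character(nrow(V)), con)
    writeLines(sprintf("%s %d", comment, f), con)
    writeLines(sprintf("C %.6f %.6f %.6f", V[, 1], V[, 2], V[, 3]), con)
  }
  invisible(path)
}
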