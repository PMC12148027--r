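# Delimited-table interchange for trials: one row per frame, a `time_s`
# column plus one column per channel component, SI units, NaN for gaps.
# Values are written with 17 significant digits so a write/read round trip
# reproduces every channel to full stored precision.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NaN"
  out
}

write_numeric_table <- function(df, path) {
  out <- as.data.frame(lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  }), stringsAsFactors = FALSE, check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
}

#' Write a trial to delimited text tables
#'
#' Writes `markers.tsv` (time + `<marker>_<x|y|z>` columns, m),
#' `forces.tsv` (time + GRF/CoP/perturbation-force columns, N and m),
#' `perturbations.tsv` (onset_s, direction, magnitude_pct_bw, duration_s)
#' and `meta.tsv` (key/value) into `dir`.
#'
#' @param trial a `trial_timeseries`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trial_tables <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(trial$markers)) {
    cols <- list(time_s = trial$marker_time)
    for (nm in names(trial$markers)) {
      m <- trial$markers[[nm]]
      for (c in 1:3) {
        cols[[paste0(nm, "_", c("x", "y", "z")[c])]] <- m[, c]
      }
    }
    write_numeric_table(as.data.frame(cols), file.path(dir, "markers.tsv"))
  }
  if (!is.null(trial$forces)) {
    df <- cbind(data.frame(time_s = trial$force_time), trial$forces)
    write_numeric_table(df, file.path(dir, "forces.tsv"))
  }
  pert <- trial$perturbations
  if (is.null(pert) || !nrow(pert)) {
    pert <- data.frame(onset_s = numeric(), direction = character(),
                       magnitude_pct_bw = numeric(), duration_s = numeric())
  }
  write_numeric_table(pert[, intersect(c("onset_s", "direction",
                                         "magnitude_pct_bw", "duration_s"),
                                       names(pert)), drop = FALSE],
                      file.path(dir, "perturbations.tsv"))
  meta <- trial$meta
  write_numeric_table(data.frame(key = names(meta),
                                 value = vapply(meta, function(v)
                                   if (is.numeric(v)) fmt_num(v) else
                                     as.character(v), character(1))),
                      file.path(dir, "meta.tsv"))
  invisible(dir)
}

#' Read a trial from delimited text tables
#'
#' Inverse of [write_trial_tables()].
#'
#' @param dir directory containing the trial tables.
#' @return a `trial_timeseries`.
#' @export
read_trial_tables <- function(dir) {
  out <- list()
  meta_df <- data.table::fread(file.path(dir, "meta.tsv"), sep = "\t",
                               colClasses = "character", data.table = FALSE)
  meta <- as.list(meta_df$value)
  names(meta) <- meta_df$key
  for (k in c("treadmill_speed", "marker_rate", "force_rate", "body_mass",
              "duration")) {
    if (!is.null(meta[[k]])) meta[[k]] <- as.numeric(meta[[k]])
  }
  out$meta <- meta
  mpath <- file.path(dir, "markers.tsv")
  if (file.exists(mpath)) {
    md <- data.table::fread(mpath, sep = "\t", data.table = FALSE)
    out$marker_time <- md$time_s
    stems <- unique(sub("_[xyz]$", "", setdiff(names(md), "time_s")))
    out$markers <- lapply(stats::setNames(stems, stems), function(nm) {
      as.matrix(md[, paste0(nm, "_", c("x", "y", "z"))])
    })
  }
  fpath <- file.path(dir, "forces.tsv")
  if (file.exists(fpath)) {
    fd <- data.table::fread(fpath, sep = "\t", data.table = FALSE)
    out$force_time <- fd$time_s
    out$forces <- fd[, setdiff(names(fd), "time_s"), drop = FALSE]
  }
  ppath <- file.path(dir, "perturbations.tsv")
  if (file.exists(ppath)) {
    out$perturbations <- data.table::fread(ppath, sep = "\t", data.table = FALSE)
  }
  structure(out, class = "trial_timeseries")
}
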