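# Plain-text cohort and stage-series storage.
#
# Formats (all interoperable, all self-validating on read):
#   region_table.csv  index,label,hemisphere,homologue_index
#   metadata.csv      subject_id,age,sex,group   (sex coded +1/-1)
#   matrix_*.tsv      full symmetric N x N matrix, tab-separated, no header
#   manifest.json     relative paths tying the above together
# Doubles are written with 17 significant digits so write -> read is the
# identity on every value.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  ix <- is.finite(x) & x == round(x) & abs(x) < 2^53
  out[ix] <- sprintf("%.0f", x[ix])
  out
}

write_matrix_tsv <- function(W, path) {
  lines <- apply(W, 1, function(r) paste(fmt_num(r), collapse = "\t"))
  writeLines(lines, path)
}

read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "numeric")
  unname(as.matrix(dt))
}

#' Write a cohort to a directory of plain-text files
#'
#' Writes the region table and per-subject metadata as CSV, each matrix as a
#' full symmetric TSV, and a JSON manifest referencing all files. Matrices
#' are stored in full (not triangular) so the format is self-validating: the
#' reader re-checks symmetry rather than trusting it.
#'
#' @param cohort A [cohort()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest path, invisibly usable by [read_cohort()].
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!inherits(cohort, "cohort")) stop("`cohort` must be a cohort object",
                                        call. = FALSE)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir,
                                 call. = FALSE)
  rt_file <- "region_table.csv"
  data.table::fwrite(cohort$region_table, file.path(out_dir, rt_file))
  manifest <- list(region_table = rt_file)
  n_sub <- length(cohort$subjects)
  if (n_sub > 0) {
    meta <- data.frame(
      subject_id = cohort_ids(cohort),
      age = fmt_num(cohort_ages(cohort)),
      sex = as.integer(cohort_sexes(cohort)),
      group = vapply(cohort$subjects, `[[`, character(1), "group")
    )
    data.table::fwrite(meta, file.path(out_dir, "metadata.csv"))
    manifest$metadata <- "metadata.csv"
    mats <- sprintf("matrix_%03d.tsv", seq_len(n_sub))
    for (k in seq_len(n_sub)) {
      write_matrix_tsv(cohort$subjects[[k]]$W, file.path(out_dir, mats[k]))
    }
    manifest$matrices <- as.list(stats::setNames(mats, meta$subject_id))
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  manifest_path
}

#' Read a cohort from a manifest
#'
#' Inverse of [write_cohort()]. Every matrix is validated against the
#' connectome invariants (symmetry, non-negativity, zero diagonal) and
#' against the region-table dimension; violations abort the read.
#'
#' @param manifest_path Path to a `manifest.json` written by [write_cohort()].
#' @param tol Symmetry tolerance passed to [validate_connectome()].
#' @return A [cohort()].
#' @export
read_cohort <- function(manifest_path, tol = 1e-9) {
  if (!file.exists(manifest_path)) stop("missing file: ", manifest_path,
                                        call. = FALSE)
  dir <- dirname(manifest_path)
  manifest <- jsonlite::read_json(manifest_path)
  need <- function(rel) {
    p <- file.path(dir, rel)
    if (!file.exists(p)) stop("missing file: ", p, call. = FALSE)
    p
  }
  rt <- tibble::as_tibble(data.table::fread(need(manifest$region_table)))
  rt$index <- as.integer(rt$index)
  rt$homologue_index <- as.integer(rt$homologue_index)
  validate_region_table(rt)
  subjects <- list()
  if (!is.null(manifest$metadata)) {
    meta <- data.table::fread(need(manifest$metadata),
                              colClasses = list(character = "subject_id"))
    mats <- manifest$matrices
    for (k in seq_len(nrow(meta))) {
      id <- meta$subject_id[k]
      W <- read_matrix_tsv(need(mats[[id]]))
      if (nrow(W) != nrow(rt) || ncol(W) != nrow(rt)) {
        stop(sprintf("matrix for subject %s is %dx%d but region table has %d regions",
                     id, nrow(W), ncol(W), nrow(rt)), call. = FALSE)
      }
      rep <- validate_connectome(W, tol = tol)
      if (nrow(rep) > 0) {
        stop(sprintf("matrix for subject %s violates invariants (%s at [%d,%d])",
                     id, rep$type[1], rep$i[1], rep$j[1]), call. = FALSE)
      }
      subjects[[k]] <- connectome(id, meta$age[k], meta$sex[k], meta$group[k], W)
    }
  }
  cohort(rt, subjects)
}

#' Write a simulated stage series
#'
#' One matrix TSV per stage (`stage_SS.tsv`), a CSV of infection vectors
#' (columns `stage, region_0..region_{N-1}`) when infection states are
#' present, and a small JSON of per-stage metadata.
#'
#' @param series A `stage_series` as returned by [simulate_disease()] or
#'   [simulate_normal_aging()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_stage_series <- function(series, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir,
                                 call. = FALSE)
  stages <- vapply(series$stages, `[[`, numeric(1), "stage")
  for (rec in series$stages) {
    write_matrix_tsv(rec$W, file.path(out_dir, sprintf("stage_%02d.tsv",
                                                       rec$stage)))
  }
  has_x <- !is.null(series$stages[[1]]$x)
  if (has_x) {
    n <- length(series$stages[[1]]$x)
    xmat <- t(vapply(series$stages, function(r) r$x, numeric(n)))
    df <- data.frame(stage = stages, xmat)
    names(df) <- c("stage", sprintf("region_%d", seq_len(n) - 1L))
    for (cn in names(df)[-1]) df[[cn]] <- fmt_num(df[[cn]])
    data.table::fwrite(df, file.path(out_dir, "infection.csv"))
  }
  meta <- list(subject_id = series$subject_id,
               sex = if (is.null(series$sex)) 1 else series$sex,
               stages = stages,
               ages = fmt_num(vapply(series$stages, `[[`, numeric(1), "age")))
  jsonlite::write_json(meta, file.path(out_dir, "series.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Read a stage series written by [write_stage_series()]
#'
#' @param dir Directory containing `series.json` and `stage_*.tsv` files.
#' @return A `stage_series` object.
#' @export
read_stage_series <- function(dir) {
  meta_path <- file.path(dir, "series.json")
  if (!file.exists(meta_path)) stop("missing file: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  xcsv <- file.path(dir, "infection.csv")
  xdf <- if (file.exists(xcsv)) data.table::fread(xcsv) else NULL
  stages <- lapply(seq_along(meta$stages), function(k) {
    s <- meta$stages[k]
    rec <- list(stage = as.integer(s),
                t = max(meta$stages) - s,
                age = as.numeric(meta$ages[k]),
                W = read_matrix_tsv(file.path(dir, sprintf("stage_%02d.tsv", s))),
                x = NULL)
    if (!is.null(xdf)) {
      rec$x <- as.numeric(xdf[xdf$stage == s, -1])
    }
    rec
  })
  structure(list(subject_id = meta$subject_id,
                 sex = if (is.null(meta$sex)) 1 else meta$sex,
                 stages = stages),
            class = "stage_series")
}
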