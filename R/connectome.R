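#' Create a connectome object
#'
#' A connectome is one subject's symmetric, non-negative region-by-region
#' streamline-count matrix together with demographics. Sex is coded `+1`
#' (male) / `-1` (female), the convention used by the link-wise aging
#' regression. The binary adjacency (`w_ij > 0`) is always derived from `W`,
#' never stored.
#'
#' @param subject_id Subject identifier (string).
#' @param age Age in years (positive).
#' @param sex `+1` for male, `-1` for female (strings `"M"`/`"F"` accepted).
#' @param group Group label (e.g. `"control"`, `"patient"`).
#' @param W Square numeric matrix of non-negative weights, zero diagonal.
#' @return An object of class `connectome`.
#' @export
connectome <- function(subject_id, age, sex, group, W) {
  if (!is.matrix(W) || !is.numeric(W) || nrow(W) != ncol(W)) {
    stop("`W` must be a square numeric matrix", call. = FALSE)
  }
  sex <- code_sex(sex)
  if (!is.numeric(age) || length(age) != 1 || age <= 0) {
    stop("`age` must be a positive number of years", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), age = as.numeric(age),
         sex = sex, group = as.character(group), W = unname(W)),
    class = "connectome"
  )
}

# Map "M"/"F" (or +1/-1) onto the regression coding +1/-1.
code_sex <- function(sex) {
  if (is.character(sex)) {
    sex <- match.arg(toupper(sex), c("M", "F"))
    return(if (sex == "M") 1 else -1)
  }
  if (!sex %in% c(1, -1)) stop("`sex` must be +1/-1 or \"M\"/\"F\"",
                               call. = FALSE)
  as.numeric(sex)
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %s: %d regions, age %.1f, sex %+d, group %s\n",
              x$subject_id, nrow(x$W), x$age, x$sex, x$group))
  invisible(x)
}

#' Validate a connectome matrix
#'
#' Reports every violation of the connectome invariants: symmetry (within
#' `tol`), elementwise non-negativity and a zero diagonal. An empty report
#' means the connectome is valid.
#'
#' @param c A [connectome()] object (or a bare matrix).
#' @param tol Absolute tolerance for symmetry checks.
#' @return A tibble with columns `type`, `i`, `j` (0-based indices) and
#'   `value`; zero rows iff valid.
#' @export
validate_connectome <- function(c, tol = 1e-9) {
  W <- if (inherits(c, "connectome")) c$W else c
  viol <- list()
  asym <- abs(W - t(W)) > tol
  asym[lower.tri(asym, diag = TRUE)] <- FALSE
  if (any(asym)) {
    idx <- unname(which(asym, arr.ind = TRUE))
    viol$sym <- tibble::tibble(type = "asymmetry", i = idx[, 1] - 1L,
                               j = idx[, 2] - 1L,
                               value = abs(W - t(W))[idx])
  }
  neg <- unname(which(W < -tol, arr.ind = TRUE))
  if (nrow(neg) > 0) {
    viol$neg <- tibble::tibble(type = "negative", i = neg[, 1] - 1L,
                               j = neg[, 2] - 1L, value = W[neg])
  }
  d <- which(abs(diag(W)) > tol)
  if (length(d) > 0) {
    viol$diag <- tibble::tibble(type = "nonzero_diagonal", i = d - 1L,
                                j = d - 1L, value = diag(W)[d])
  }
  if (length(viol) == 0) {
    tibble::tibble(type = character(), i = integer(), j = integer(),
                   value = numeric())
  } else {
    dplyr::bind_rows(viol)
  }
}

#' Assemble a cohort
#'
#' A cohort is an ordered collection of connectomes sharing one region table.
#'
#' @param region_table Atlas tibble, see [generate_atlas()].
#' @param subjects List of [connectome()] objects, all of matching dimension.
#' @return An object of class `cohort`.
#' @export
cohort <- function(region_table, subjects) {
  validate_region_table(region_table)
  n <- nrow(region_table)
  for (s in subjects) {
    if (!inherits(s, "connectome")) stop("subjects must be connectome objects",
                                         call. = FALSE)
    if (nrow(s$W) != n) {
      stop(sprintf("subject %s has %d regions but the region table has %d",
                   s$subject_id, nrow(s$W), n), call. = FALSE)
    }
  }
  structure(list(region_table = region_table, subjects = subjects),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects on %d regions\n",
              length(x$subjects), nrow(x$region_table)))
  invisible(x)
}

#' @export
length.cohort <- function(x) length(x$subjects)

# Convenience accessors used throughout the pipeline.
cohort_ages <- function(cohort) vapply(cohort$subjects, `[[`, numeric(1), "age")
cohort_sexes <- function(cohort) vapply(cohort$subjects, `[[`, numeric(1), "sex")
cohort_ids <- function(cohort) vapply(cohort$subjects, `[[`, character(1),
                                      "subject_id")

#' Subset a cohort by subject position
#'
#' @param cohort A [cohort()].
#' @param idx Integer positions (1-based, R convention) of subjects to keep.
#' @return A new cohort with the selected subjects, in the given order.
#' @export
cohort_subset <- function(cohort, idx) {
  cohort(cohort$region_table, cohort$subjects[idx])
}
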