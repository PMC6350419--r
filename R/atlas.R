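#' Build a bilateral region atlas
#'
#' Constructs a deterministic region table for a bilateral parcellation with
#' `n_region_pairs` left/right homologue pairs (default 41 pairs, i.e. 82
#' regions). Region `2k` is the left member of pair `k` and region `2k + 1`
#' its right (contralateral) twin. Indices are 0-based and are the single
#' source of region ordering for every matrix in the package.
#'
#' @param n_region_pairs Number of homologue pairs; must be at least 2.
#' @return A tibble with columns `index`, `label`, `hemisphere` (`"L"`/`"R"`)
#'   and `homologue_index`.
#' @examples
#' generate_atlas(2)
#' @export
generate_atlas <- function(n_region_pairs = 41) {
  if (!is.numeric(n_region_pairs) || length(n_region_pairs) != 1 ||
      n_region_pairs < 2 || n_region_pairs != round(n_region_pairs)) {
    stop("`n_region_pairs` must be a single integer >= 2", call. = FALSE)
  }
  n_region_pairs <- as.integer(n_region_pairs)
  n <- 2L * n_region_pairs
  idx <- seq_len(n) - 1L
  pair <- idx %/% 2L
  hemi <- ifelse(idx %% 2L == 0L, "L", "R")
  tibble::tibble(
    index = idx,
    label = sprintf("A%02d%s", pair + 1L, hemi),
    hemisphere = hemi,
    homologue_index = ifelse(idx %% 2L == 0L, idx + 1L, idx - 1L)
  )
}

# Stop unless `rt` is a structurally valid region table.
validate_region_table <- function(rt) {
  need <- c("index", "label", "hemisphere", "homologue_index")
  if (!is.data.frame(rt) || !all(need %in% names(rt))) {
    stop("region table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(rt)
  if (n %% 2L != 0L) stop("region table must have an even number of regions",
                          call. = FALSE)
  if (!identical(as.integer(rt$index), seq_len(n) - 1L)) {
    stop("region indices must be contiguous 0..N-1 in order", call. = FALSE)
  }
  if (anyDuplicated(rt$label)) stop("region labels must be unique", call. = FALSE)
  h <- as.integer(rt$homologue_index)
  if (any(h < 0L | h >= n) || any(h == rt$index) ||
      !identical(h[h + 1L], as.integer(rt$index))) {
    stop("homologue mapping must be a fixed-point-free involution",
         call. = FALSE)
  }
  invisible(rt)
}

#' All bilateral seed-candidate pairs of an atlas
#'
#' @param region_table Atlas tibble.
#' @return 2-column matrix of 0-based (left, right) region indices, one row
#'   per homologue pair.
#' @export
atlas_seed_pairs <- function(region_table) {
  left <- region_table$index[region_table$hemisphere == "L"]
  cbind(left, region_table$homologue_index[left + 1L], deparse.level = 0)
}

#' Seed pair (region, homologue) for a region label
#'
#' @param region_table Atlas tibble.
#' @param label A region label from the table.
#' @return Length-2 vector of 0-based indices.
#' @export
seed_pair_for_label <- function(region_table, label) {
  i <- match(label, region_table$label)
  if (is.na(i)) stop("unknown region label: ", label, call. = FALSE)
  c(region_table$index[i], region_table$homologue_index[i])
}
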