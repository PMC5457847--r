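#' Normalize a mature miRNA name to a cross-species key
#'
#' Strips a leading lowercase three-letter species prefix (`hsa-`, `rno-`,
#' `mmu-`, ...) when the remainder still looks like a miRNA name, then
#' lowercases. Arm suffixes (`-5p`/`-3p`) are preserved verbatim. The
#' normalization is idempotent and never leaves a species prefix in the key,
#' so `hsa-miR-182` and `rno-miR-182` map to the same key `mir-182`.
#'
#' @param id Character vector of miRNA identifiers (all nonempty).
#' @return Character vector of normalized keys.
#' @export
normalize_mirna_name <- function(id) {
  id <- as.character(id)
  if (any(is.na(id) | !nzchar(id))) {
    stop("miRNA ids must be nonempty", call. = FALSE)
  }
  has_prefix <- grepl("^[a-z]{3}-", id) &
    grepl("^(mir|let|lin|bantam)", tolower(sub("^[a-z]{3}-", "", id)))
  stripped <- ifelse(has_prefix, sub("^[a-z]{3}-", "", id), id)
  tolower(stripped)
}

#' Match DE miRNAs across species
#'
#' Joins two DE miRNA tables on the normalized mature name and reports the
#' per-species direction and whether the directions agree.
#'
#' @param set_a,set_b Tibbles with a miRNA id column (`mirna` or `feature`)
#'   and a `direction` column.
#' @param collapse_arms Also strip `-5p`/`-3p` arm suffixes before matching
#'   (default `FALSE`: arms must match exactly).
#' @return Tibble: `key`, `id_a`, `id_b`, `direction_a`, `direction_b`,
#'   `concordant`.
#' @export
shared_demirs <- function(set_a, set_b, collapse_arms = FALSE) {
  norm_tbl <- function(tbl, suffix) {
    ids <- if ("mirna" %in% names(tbl)) tbl$mirna else tbl$feature
    key <- normalize_mirna_name(ids)
    if (collapse_arms) key <- sub("-(5p|3p)$", "", key)
    out <- tibble::tibble(key = key, id = ids, direction = tbl$direction) |>
      dplyr::distinct(.data$key, .keep_all = TRUE)
    names(out)[2:3] <- paste0(c("id", "direction"), suffix)
    out
  }
  dplyr::inner_join(norm_tbl(set_a, "_a"), norm_tbl(set_b, "_b"),
                    by = "key") |>
    dplyr::mutate(concordant = .data$direction_a == .data$direction_b) |>
    dplyr::arrange(.data$key)
}
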