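#' The four variable groups
#'
#' Clinical features are partitioned into four domains: oncological
#' history (`Onco`: prior treatment, tumor origin, spread), pathological
#' (`Path`: grade, Ki-67, differentiation), immunohistochemical
#' (`Imm`: CK7, CK20, TTF1, ...) and laboratory (`Lab`: CEA, CA19-9,
#' AFP, chromogranin A, NSE).
#'
#' @return Character vector of the four group labels.
#' @export
variable_groups <- function() c("Onco", "Path", "Imm", "Lab")

#' Enumerate all non-empty variable-group subsets
#'
#' Models are benchmarked on every non-empty combination of the variable
#' groups (15 combinations for the four standard groups). Order is
#' deterministic: by subset size, then lexicographically.
#'
#' @param groups Character vector of distinct group labels
#'   (default [variable_groups()]).
#' @return A list of character vectors, length `2^k - 1`.
#' @examples
#' length(enumerate_group_subsets()) # 15
#' @export
enumerate_group_subsets <- function(groups = variable_groups()) {
  stop_if_not(is.character(groups) && length(groups) >= 1L,
              "`groups` must be a non-empty character vector.")
  stop_if_not(!anyDuplicated(groups), "`groups` must be distinct.")
  subsets <- unlist(
    lapply(seq_along(groups), function(k) {
      cols <- utils::combn(sort(groups), k, simplify = FALSE)
      cols[order(map_chr(cols, paste, collapse = "+"))]
    }),
    recursive = FALSE
  )
  subsets
}

subset_label <- function(groups) paste(sort(groups), collapse = "+")
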