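#' Behaviour categories and activity levels
#'
#' The ethogram used throughout the package consists of seven non-overlapping
#' behaviour categories: three static postures (`lay`, `sit`, `stand`) and
#' four gaits of increasing dynamics (`walk`, `trot`, `canter`, `gallop`).
#' Each category carries an ad-hoc activity level A in 0..3 used to grade
#' misclassifications by the absolute level difference
#' \eqn{\Delta A = |A_{out} - A_{in}|}: the static postures are level 0,
#' walk 1, trot 2, canter and gallop 3.
#'
#' @return `behavior_categories()` returns the character vector of the seven
#'   category names in canonical order. `activity_level()` returns the
#'   integer level(s) of `category`.
#' @examples
#' behavior_categories()
#' activity_level(c("walk", "gallop"))
#' @export
behavior_categories <- function() {
  c("lay", "sit", "stand", "walk", "trot", "canter", "gallop")
}

.ACTIVITY_LEVELS <- c(
  lay = 0L, sit = 0L, stand = 0L,
  walk = 1L, trot = 2L, canter = 3L, gallop = 3L
)

#' @param category character vector of category names.
#' @rdname behavior_categories
#' @export
activity_level <- function(category) {
  category <- as.character(category)
  bad <- setdiff(unique(category), behavior_categories())
  if (length(bad) > 0L) {
    stop("unknown behaviour category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(.ACTIVITY_LEVELS[category])
}

#' @param x character vector to coerce.
#' @rdname behavior_categories
#' @export
behavior_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), behavior_categories())
  if (length(bad) > 0L) {
    stop("unknown behaviour category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = behavior_categories())
}
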