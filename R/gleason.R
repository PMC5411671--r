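#' Gleason score (ordered pair) utilities
#'
#' A Gleason score is an ordered pair of architectural patterns
#' (primary + secondary), each in \{3, 4, 5\}. Pairs are stored as integer
#' codes `10 * primary + secondary`, e.g. `34` for Gleason 3+4. Scores are
#' ordered by total first and, for equal totals, by primary pattern, so that
#' 3+3 < 3+4 < 4+3 < 4+4 < 4+5 < 5+4 < 5+5 — the ordering used in clinical
#' risk definitions (4+3 outranks 3+4).
#'
#' @param primary,secondary Gleason patterns in \{3, 4, 5\}.
#' @return `gleason_pair()` returns an integer pair code.
#' @export
#' @examples
#' gleason_pair(3, 4)           # 34
#' gleason_rank(43) > gleason_rank(34)
#' gleason_label(43)            # "4+3"
gleason_pair <- function(primary, secondary) {
  primary <- as.integer(primary); secondary <- as.integer(secondary)
  if (any(!primary %in% 3:5) || any(!secondary %in% 3:5))
    stop("Gleason patterns must be in {3, 4, 5}")
  10L * primary + secondary
}

#' @param pair Integer pair code(s) as returned by [gleason_pair()].
#' @rdname gleason_pair
#' @export
gleason_primary <- function(pair) as.integer(pair) %/% 10L

#' @rdname gleason_pair
#' @export
gleason_secondary <- function(pair) as.integer(pair) %% 10L

#' @rdname gleason_pair
#' @export
gleason_total <- function(pair) gleason_primary(pair) + gleason_secondary(pair)

#' @rdname gleason_pair
#' @export
gleason_label <- function(pair) {
  ifelse(is.na(pair), NA_character_,
         paste0(gleason_primary(pair), "+", gleason_secondary(pair)))
}

#' Parse labels like "3+4" into pair codes
#' @param label Character vector of `"p+s"` labels.
#' @rdname gleason_pair
#' @export
gleason_parse <- function(label) {
  parts <- strsplit(trimws(label), "\\+")
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed Gleason label: ", paste(label[bad], collapse = ", "))
  p <- as.integer(vapply(parts, `[`, "", 1L))
  s <- as.integer(vapply(parts, `[`, "", 2L))
  gleason_pair(p, s)
}

#' Rank of a Gleason score for ordering (total, then primary)
#' @rdname gleason_pair
#' @export
gleason_rank <- function(pair) 10L * gleason_total(pair) + gleason_primary(pair)

#' Highest Gleason score among a set of pair codes
#' @param pairs Integer vector of pair codes.
#' @rdname gleason_pair
#' @export
gleason_max <- function(pairs) {
  pairs <- pairs[!is.na(pairs)]
  if (!length(pairs)) return(NA_integer_)
  pairs[which.max(gleason_rank(pairs))]
}

#' Classify lesion Gleason heterogeneity
#'
#' A lesion is homogeneous when all its cores carry one Gleason designation and
#' heterogeneous otherwise. Two criteria are supported:
#' \describe{
#'   \item{`"grades"`}{(primary criterion) heterogeneous iff more than one
#'     distinct ordered pair is present; 3+4 and 4+3 in different areas of the
#'     same lesion count as heterogeneity.}
#'   \item{`"score"`}{(secondary criterion) pairs with equal totals are
#'     identified, so a lesion mixing only 3+4 and 4+3 is homogeneous.}
#' }
#'
#' @param composition Integer vector of Gleason pair codes present in the
#'   lesion (duplicates allowed; at least one value).
#' @param criterion `"grades"` or `"score"`.
#' @return Logical: `TRUE` if heterogeneous.
#' @export
#' @examples
#' classify_heterogeneity(c(34, 43), "grades")  # TRUE
#' classify_heterogeneity(c(34, 43), "score")   # FALSE
classify_heterogeneity <- function(composition, criterion = c("grades", "score")) {
  criterion <- match.arg(criterion)
  composition <- unique(composition[!is.na(composition)])
  if (!length(composition)) stop("empty grade composition")
  if (criterion == "grades") length(composition) > 1L
  else length(unique(gleason_total(composition))) > 1L
}
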