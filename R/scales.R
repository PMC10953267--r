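#' Define a multi-item scale
#'
#' A scale is a named set of Likert items belonging to one construct
#' (maternal parenting practice or adolescent mental-health problem), with an
#' integer response range and an optional subset of reverse-keyed items.
#'
#' @param name scale name (used as the node label in networks).
#' @param construct one of `"parenting"` or `"mental_health"`.
#' @param item_ids character vector of item column stems (wave suffixes are
#'   appended by the I/O layer).
#' @param response_range integer pair `c(lo, hi)` of admissible responses.
#' @param reverse_keyed subset of `item_ids` scored as `lo + hi - x`.
#' @return an object of class `scale_definition`.
#' @examples
#' scale_definition("warmth", "parenting", paste0("warmth_i", 1:8), c(1, 5))
#' @export
scale_definition <- function(name, construct = c("parenting", "mental_health"),
                             item_ids, response_range = c(1L, 5L),
                             reverse_keyed = character()) {
  construct <- match.arg(construct)
  if (length(item_ids) < 1L) pn_config_error("scale '%s': item_ids must be non-empty", name)
  if (!all(reverse_keyed %in% item_ids))
    pn_config_error("scale '%s': reverse_keyed items not all in item_ids", name)
  if (length(response_range) != 2L || response_range[1] >= response_range[2])
    pn_config_error("scale '%s': response_range must be (lo, hi) with lo < hi", name)
  structure(
    list(name = name, construct = construct, item_ids = as.character(item_ids),
         response_range = as.numeric(response_range),
         reverse_keyed = as.character(reverse_keyed)),
    class = "scale_definition"
  )
}

#' Scale definitions for the two-wave parenting / mental-health study design
#'
#' Nine scales: five maternal parenting practices rated 1-5 (warmth 8 items,
#' monitoring 6, hostility 6, inductive reasoning 5, harshness 3) and four
#' adolescent mental-health problems (trait anxiety, 20 items rated 1-4;
#' depression, 27 items rated 0-2; aggression and conduct problems from a
#' youth self-report instrument, rated 0-2). A four-item consistent-discipline
#' scale can be included for reliability-screening demonstrations; it is
#' excluded by default because scales of its kind fail the alpha >= 0.60
#' screen.
#'
#' @param include_discipline also return the consistent-discipline scale.
#' @return named list of [scale_definition()] objects.
#' @export
study_scales <- function(include_discipline = FALSE) {
  mk <- function(name, construct, k, range)
    scale_definition(name, construct, paste0(name, "_i", seq_len(k)), range)
  defs <- list(
    anxiety    = mk("anxiety",    "mental_health", 20L, c(1, 4)),
    depression = mk("depression", "mental_health", 27L, c(0, 2)),
    aggression = mk("aggression", "mental_health", 17L, c(0, 2)),
    conduct    = mk("conduct",    "mental_health", 15L, c(0, 2)),
    warmth     = mk("warmth",     "parenting",      8L, c(1, 5)),
    monitoring = mk("monitoring", "parenting",      6L, c(1, 5)),
    hostility  = mk("hostility",  "parenting",      6L, c(1, 5)),
    reasoning  = mk("reasoning",  "parenting",      5L, c(1, 5)),
    harshness  = mk("harshness",  "parenting",      3L, c(1, 5))
  )
  if (include_discipline)
    defs$discipline <- mk("discipline", "parenting", 4L, c(1, 5))
  defs
}

# construct tag lookup for a set of scale definitions
constructs_of <- function(scale_defs) {
  vapply(scale_defs, function(d) d$construct, character(1))
}
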