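#' Marker registry
#'
#' The registry names the markers a recording must carry and assigns each a
#' role: `body` (trunk, right arm, hand), `instrument` (cello), or `bow`.
#' The default registry follows the standard cello-bowing marker set: trunk
#' (sternum, C7), right arm (acromion, lateral elbow epicondyle, forearm,
#' wrist), hand (first MCP and first PIP joints), three cello markers (scroll
#' and tailpiece defining the string axis, one on the body defining the
#' lateral axis) and two bow markers (tip, and a proximal marker roughly
#' two-thirds of the way from tip to frog).
#'
#' @param names Character vector of marker names.
#' @param roles Character vector, one of `"body"`, `"instrument"`, `"bow"`
#'   per marker.
#' @return A tibble with columns `name` and `role`, class `bow_registry`.
#' @examples
#' marker_registry()
#' @export
marker_registry <- function(names = NULL, roles = NULL) {
  if (is.null(names)) {
    names <- c(
      "sternum", "c7", "acromion", "elbow_lat", "forearm", "wrist",
      "hand_mcp1", "hand_pip1",
      "cello_scroll", "cello_tail", "cello_body",
      "bow_tip", "bow_mid"
    )
    roles <- c(rep("body", 8), rep("instrument", 3), rep("bow", 2))
  }
  stopifnot(length(names) == length(roles))
  if (anyDuplicated(names)) {
    abort("marker names must be unique")
  }
  roles <- match.arg(roles, c("body", "instrument", "bow"), several.ok = TRUE)
  reg <- tibble::tibble(name = as.character(names), role = roles)
  if (sum(reg$role == "bow") != 2) {
    abort("registry must contain exactly 2 bow markers")
  }
  if (sum(reg$role == "instrument") != 3) {
    abort("registry must contain exactly 3 instrument markers")
  }
  required <- c(
    "sternum", "c7", "acromion", "elbow_lat", "forearm", "wrist",
    "hand_mcp1", "hand_pip1"
  )
  missing <- setdiff(required, reg$name)
  if (length(missing) > 0) {
    abort(paste0(
      "registry is missing required body marker(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  class(reg) <- c("bow_registry", class(reg))
  reg
}
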