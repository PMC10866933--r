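#' Marker panel
#'
#' An ordered antibody panel with a role per marker. Markers with role
#' `"phenotyping"` enter clustering; `"nuclear"` markers are used only for
#' segmentation upstream and are excluded from phenotyping, mirroring the
#' common IMC practice of clustering on a selected non-nuclear subset;
#' `"functional"` markers are carried through but not clustered on.
#'
#' @param markers character vector of unique marker names (panel order).
#' @param roles character vector, one of `"phenotyping"`, `"nuclear"`,
#'   `"functional"` per marker. Defaults to all phenotyping.
#' @return a `marker_panel` data.frame with columns `marker` and `role`.
#' @export
marker_panel <- function(markers, roles = rep("phenotyping", length(markers))) {
  markers <- as.character(markers)
  if (anyDuplicated(markers)) stop_fmt("marker names must be unique")
  roles <- match.arg(roles, c("phenotyping", "nuclear", "functional"),
                     several.ok = TRUE)
  roles <- rep_len(roles, length(markers))
  if (!any(roles == "phenotyping")) {
    stop_fmt("panel must contain at least one phenotyping marker")
  }
  structure(data.frame(marker = markers, role = roles,
                       stringsAsFactors = FALSE),
            class = c("marker_panel", "data.frame"))
}

#' Default synthetic panel of 32 phenotyping markers
#'
#' @param n_markers panel size.
#' @return a [marker_panel()].
#' @export
default_marker_panel <- function(n_markers = 32L) {
  marker_panel(sprintf("marker_%02d", seq_len(n_markers)))
}

#' Phenotyping marker names of a panel
#' @param panel a [marker_panel()].
#' @return character vector.
#' @export
phenotyping_markers <- function(panel) {
  panel$marker[panel$role == "phenotyping"]
}

#' Read / write a marker panel as YAML
#' @param panel a [marker_panel()].
#' @param path file path.
#' @return `read_panel` returns a [marker_panel()]; `write_panel` returns
#'   `path` invisibly.
#' @export
write_panel <- function(panel, path) {
  yaml::write_yaml(list(markers = as.list(stats::setNames(panel$role,
                                                          panel$marker))),
                   path)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$markers)) stop_fmt("panel file %s has no 'markers' block", path)
  marker_panel(names(y$markers), unlist(y$markers, use.names = FALSE))
}
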