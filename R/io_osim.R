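#' Import a parameter subset from an OpenSim-style .osim XML file
#'
#' Reads segment masses/inertias from \code{Body} elements and the four
#' Hill parameters (maximum isometric force, optimal fiber length, tendon
#' slack length, maximum contraction velocity) from Thelen-style muscle
#' elements. Geometry, wrapping surfaces and path points are outside the
#' planar engine's scope and are skipped with a notice. The result is a
#' partial model: a parameter table to merge into a packaged model, not a
#' standalone \code{msk_model}.
#'
#' @param path .osim file path.
#' @param quiet suppress the skipped-elements notice.
#' @return list with \code{bodies} (data.frame: name, mass, inertia_xx/yy/zz)
#'   and \code{muscles} (data.frame: name, F0, lopt, lslack, vmax).
#' @export
import_osim_subset <- function(path, quiet = FALSE) {
  doc <- xml2::read_xml(path)
  bnodes <- xml2::xml_find_all(doc, ".//Body")
  num1 <- function(node, tag) {
    v <- xml2::xml_text(xml2::xml_find_first(node, paste0("./", tag)))
    suppressWarnings(as.numeric(trimws(v)))
  }
  bodies <- do.call(rbind, lapply(bnodes, function(b) {
    iner <- xml2::xml_text(xml2::xml_find_first(b, "./inertia"))
    iv <- rep(NA_real_, 3L)
    if (!is.na(iner)) {
      allv <- suppressWarnings(as.numeric(strsplit(trimws(iner), "\\s+")[[1L]]))
      iv <- allv[1:3]
    } else {
      iv <- c(num1(b, "inertia_xx"), num1(b, "inertia_yy"), num1(b, "inertia_zz"))
    }
    data.frame(name = xml2::xml_attr(b, "name"), mass = num1(b, "mass"),
               inertia_xx = iv[1L], inertia_yy = iv[2L], inertia_zz = iv[3L])
  }))
  mnodes <- xml2::xml_find_all(
    doc, ".//Thelen2003Muscle | .//Millard2012EquilibriumMuscle | .//Schutte1993Muscle")
  muscles <- do.call(rbind, lapply(mnodes, function(m) {
    row <- data.frame(
      name = xml2::xml_attr(m, "name"),
      F0 = num1(m, "max_isometric_force"),
      lopt = num1(m, "optimal_fiber_length"),
      lslack = num1(m, "tendon_slack_length"),
      vmax = num1(m, "max_contraction_velocity"))
    bad <- names(row)[-1L][!is.finite(unlist(row[-1L]))]
    if (length(bad))
      stopf("muscle '%s' lacks mandatory parameter(s): %s",
            row$name, paste(bad, collapse = ", "))
    row
  }))
  skipped <- length(xml2::xml_find_all(
    doc, ".//WrapObjectSet | .//GeometryPath//ConditionalPathPoint"))
  if (!quiet && skipped > 0L)
    message(sprintf("import_osim_subset: skipped %d geometry/wrapping element(s)",
                    skipped))
  list(bodies = bodies,
       muscles = muscles %||% data.frame(name = character(0), F0 = numeric(0),
                                         lopt = numeric(0), lslack = numeric(0),
                                         vmax = numeric(0)))
}

#' Merge imported .osim parameters into a model
#'
#' Overwrites matching segment masses/inertias and muscle Hill parameters in
#' place; unmatched entries are ignored.
#'
#' @param model an \code{msk_model}.
#' @param subset result of \code{\link{import_osim_subset}}.
#' @return the updated model.
#' @export
merge_osim_subset <- function(model, subset) {
  if (!is.null(subset$bodies) && nrow(subset$bodies)) {
    i <- match(subset$bodies$name, model$segments$name)
    ok <- !is.na(i)
    model$segments$mass[i[ok]] <- subset$bodies$mass[ok]
    model$segments$izz[i[ok]] <- subset$bodies$inertia_zz[ok]
  }
  if (!is.null(model$muscles) && !is.null(subset$muscles) && nrow(subset$muscles)) {
    i <- match(subset$muscles$name, model$muscles$name)
    ok <- !is.na(i)
    for (col in c("F0", "lopt", "lslack", "vmax"))
      model$muscles[[col]][i[ok]] <- subset$muscles[[col]][ok]
  }
  model
}
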