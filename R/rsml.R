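#' Write a root system as an RSML 1.0 document
#'
#' Serializes a root system to Root System Markup Language: one `<scene>`
#' with one `<plant>` (labelled with the compartment), roots nested by
#' topology, per-root properties `branching_number`, `insertion_position`
#' (cm of arc length along the parent) and `insertion_angle` (degrees), the
#' polyline geometry in cm (6 decimal places) and a constant per-point
#' `diameter` function. No timestamps are written, so identical systems
#' serialize to identical bytes.
#'
#' @param system A `root_system`.
#' @param path Optional file path; if `NULL` the `xml_document` is returned.
#' @return The `xml_document`, invisibly when `path` is given.
#' @export
write_rsml <- function(system, path = NULL) {
  stopifnot(inherits(system, "root_system"))
  doc <- xml2::xml_new_root("rsml")
  meta <- xml2::xml_add_child(doc, "metadata")
  xml2::xml_add_child(meta, "version", "1")
  xml2::xml_add_child(meta, "unit", "cm")
  xml2::xml_add_child(meta, "software", "rootbox")
  scene <- xml2::xml_add_child(doc, "scene")
  plant <- xml2::xml_add_child(scene, "plant", id = "1",
                               label = system$compartment %||% "plant")
  ids <- vapply(system$axes, `[[`, integer(1), "id")
  parents <- vapply(system$axes, function(a)
    if (is.na(a$parent_id)) 0L else a$parent_id, integer(1))
  add_root <- function(parent_node, ax) {
    rt <- xml2::xml_add_child(parent_node, "root",
                              ID = as.character(ax$id),
                              label = sprintf("bn%d", ax$bn))
    props <- xml2::xml_add_child(rt, "properties")
    xml2::xml_add_child(props, "branching_number", as.character(ax$bn))
    xml2::xml_add_child(props, "insertion_position",
                        sprintf("%.6f", ax$insertion_arclength))
    xml2::xml_add_child(props, "insertion_angle",
                        sprintf("%.6f", ax$axial_angle))
    geom <- xml2::xml_add_child(rt, "geometry")
    pl <- xml2::xml_add_child(geom, "polyline")
    pts <- ax$points
    for (i in seq_len(nrow(pts))) {
      xml2::xml_add_child(pl, "point",
                          x = sprintf("%.6f", pts[i, 1L]),
                          y = sprintf("%.6f", pts[i, 2L]),
                          z = sprintf("%.6f", pts[i, 3L]))
    }
    fns <- xml2::xml_add_child(rt, "functions")
    fn <- xml2::xml_add_child(fns, "function", name = "diameter",
                              domain = "polyline")
    dia <- sprintf("%.6f", 2 * ax$radius)
    for (i in seq_len(nrow(pts))) {
      xml2::xml_add_child(fn, "sample", value = dia)
    }
    for (child in system$axes[parents == ax$id]) add_root(rt, child)
  }
  for (ax in system$axes[parents == 0L]) add_root(plant, ax)
  if (is.null(path)) return(doc)
  xml2::write_xml(doc, path)
  invisible(doc)
}

#' Read a root system from an RSML document
#'
#' Inverse of [write_rsml()]: recovers the topology (parent links via
#' nesting), branching numbers, insertion positions/angles, polylines and
#' diameters. Realized growth parameters are not part of RSML, so the
#' returned system carries no calibration (its biomass column is `NA` in
#' [trait_table()]); geometry-derived traits are fully recovered.
#'
#' @param x File path or `xml_document`.
#' @return A `root_system`.
#' @export
read_rsml <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else tryCatch(
    xml2::read_xml(x),
    error = function(e) stop("malformed RSML document '", x, "': ",
                             conditionMessage(e), call. = FALSE))
  if (xml2::xml_name(doc) != "rsml") stop("not an RSML document")
  ver <- xml2::xml_text(xml2::xml_find_first(doc, "./metadata/version"))
  if (!is.na(ver) && !ver %in% c("1", "1.0"))
    stop("unsupported RSML schema version: ", ver)
  plant <- xml2::xml_find_first(doc, "./scene/plant")
  axes <- list()
  walk <- function(node, parent_id) {
    for (rt in xml2::xml_find_all(node, "./root")) {
      id <- as.integer(xml2::xml_attr(rt, "ID"))
      bn <- as.integer(xml2::xml_text(
        xml2::xml_find_first(rt, "./properties/branching_number")))
      ipos <- as.numeric(xml2::xml_text(
        xml2::xml_find_first(rt, "./properties/insertion_position")))
      iang <- as.numeric(xml2::xml_text(
        xml2::xml_find_first(rt, "./properties/insertion_angle")))
      ptn <- xml2::xml_find_all(rt, "./geometry/polyline/point")
      pts <- cbind(as.numeric(xml2::xml_attr(ptn, "x")),
                   as.numeric(xml2::xml_attr(ptn, "y")),
                   as.numeric(xml2::xml_attr(ptn, "z")))
      if (!nrow(pts) || anyNA(pts))
        stop("RSML root ID ", id, ": missing or non-numeric polyline")
      dia <- as.numeric(xml2::xml_attr(
        xml2::xml_find_first(rt, "./functions/function[@name='diameter']/sample"),
        "value"))
      seg <- if (nrow(pts) > 1L)
        sqrt(rowSums((pts[-1L, , drop = FALSE] -
                        pts[-nrow(pts), , drop = FALSE])^2)) else numeric(0)
      heading <- if (length(seg) && seg[length(seg)] > 0)
        (pts[nrow(pts), ] - pts[nrow(pts) - 1L, ]) / seg[length(seg)]
      else c(0, 0, 1)
      axes[[length(axes) + 1L]] <<- list(
        id = id, bn = bn, parent_id = parent_id,
        insertion_arclength = ipos, axial_angle = iang,
        radial_angle = NA_real_, birth_time = NA_real_,
        r = NA_real_, lmax = NA_real_, ln = NA_real_,
        radius = if (is.na(dia)) NA_real_ else dia / 2,
        length = sum(seg), points = pts, heading = heading,
        sites_spawned = NA_integer_
      )
      walk(rt, id)
    }
  }
  if (!inherits(plant, "xml_missing")) walk(plant, NA_integer_)
  structure(list(
    axes = axes, box = c(20, 27, 107), barrier_gap = 4,
    origin = if (length(axes)) axes[[1L]]$points[1L, ] else c(0, 0, 0),
    compartment = if (inherits(plant, "xml_missing")) NA_character_
                  else xml2::xml_attr(plant, "label"),
    calibration = NULL, clock = NA_real_, seed = NA_integer_
  ), class = "root_system")
}

#' Export root polylines as a Wavefront OBJ file
#'
#' Writes every axis as an OBJ polyline (`l` elements over `v` vertices) for
#' quick inspection in any 3D viewer. Geometry only; no materials.
#'
#' @param system A `root_system`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(system, path) {
  stopifnot(inherits(system, "root_system"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# rootbox root system export", con)
  offset <- 0L
  for (ax in system$axes) {
    pts <- ax$points
    writeLines(sprintf("o root_%d_bn%d", ax$id, ax$bn), con)
    writeLines(sprintf("v %.6f %.6f %.6f", pts[, 1L], pts[, 2L], pts[, 3L]),
               con)
    if (nrow(pts) > 1L)
      writeLines(paste("l", paste(offset + seq_len(nrow(pts)),
                                  collapse = " ")), con)
    offset <- offset + nrow(pts)
  }
  invisible(path)
}
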