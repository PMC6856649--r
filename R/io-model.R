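# Model file I/O: a documented XML subset using .osim-4.0-flavored element
# names (OpenSimDocument, Model, BodySet/Body, JointSet/Joint,
# ForceSet/Muscle with GeometryPath/PathPointSet, WrapObjectSet,
# MarkerSet/Marker). write_model() %then% read_model() is the identity on
# all fields; unknown elements are skipped with a warning.

#' @keywords internal
.num_attr <- function(x) paste(sprintf("%.17g", x), collapse = " ")

#' @keywords internal
.parse_nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])

#' Write a shoulder model to the XML model subset
#'
#' @param model a [shoulder_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  doc <- xml2::xml_new_root("OpenSimDocument", Version = "40000")
  mdl <- xml2::xml_add_child(doc, "Model", name = model$name)
  xml2::xml_add_child(mdl, "gravity", .num_attr(model$gravity))
  xml2::xml_add_child(mdl, "hand_mass", .num_attr(model$hand_mass))
  if (!is.null(model$hand_point)) {
    hp <- xml2::xml_add_child(mdl, "hand_point", body = model$hand_point$body)
    xml2::xml_add_child(hp, "location", .num_attr(model$hand_point$loc))
  }
  bs <- xml2::xml_add_child(mdl, "BodySet")
  for (b in model$bodies) {
    bn <- xml2::xml_add_child(bs, "Body", name = b$name)
    xml2::xml_add_child(bn, "mass", .num_attr(b$mass))
    xml2::xml_add_child(bn, "mass_center", .num_attr(b$com))
    xml2::xml_add_child(bn, "inertia", .num_attr(as.numeric(b$inertia)))
  }
  js <- xml2::xml_add_child(mdl, "JointSet")
  for (j in model$joints) {
    jn <- xml2::xml_add_child(js, "Joint", name = j$name, type = j$type,
                              parent = j$parent, child = j$child)
    xml2::xml_add_child(jn, "parent_offset", .num_attr(as.numeric(j$parent_offset)))
    xml2::xml_add_child(jn, "coordinates", paste(j$coords, collapse = " "))
    if (j$type == "hinge")
      xml2::xml_add_child(jn, "axis", .num_attr(j$params$axis))
    if (j$type == "ellipsoid")
      xml2::xml_add_child(jn, "radii", .num_attr(j$params$radii))
    if (j$type == "aim") {
      xml2::xml_add_child(jn, "target_body", j$params$target_body)
      xml2::xml_add_child(jn, "target_point", .num_attr(j$params$target_point))
      xml2::xml_add_child(jn, "aim_ref", .num_attr(j$params$aim_ref))
    }
  }
  cs <- xml2::xml_add_child(mdl, "CoordinateSet")
  for (co in model$coordinates) {
    cn <- xml2::xml_add_child(cs, "Coordinate", name = co$name)
    xml2::xml_add_child(cn, "default_value", .num_attr(co$default))
    xml2::xml_add_child(cn, "range", .num_attr(co$range))
  }
  ws <- xml2::xml_add_child(mdl, "WrapObjectSet")
  for (w in model$wraps) {
    wn <- xml2::xml_add_child(ws, "WrapObject", name = w$name, kind = w$kind,
                              body = w$body)
    xml2::xml_add_child(wn, "xform", .num_attr(as.numeric(w$xform)))
    xml2::xml_add_child(wn, "dimensions", .num_attr(w$radii))
  }
  fs <- xml2::xml_add_child(mdl, "ForceSet")
  for (m in model$muscles) {
    p <- m$params
    mn <- xml2::xml_add_child(fs, "Muscle", name = p$name)
    xml2::xml_add_child(mn, "muscle_group", p$group)
    xml2::xml_add_child(mn, "max_isometric_force", .num_attr(p$f_max))
    xml2::xml_add_child(mn, "optimal_fiber_length", .num_attr(p$l_opt))
    xml2::xml_add_child(mn, "tendon_slack_length", .num_attr(p$l_ts))
    xml2::xml_add_child(mn, "pennation_angle", .num_attr(p$pennation))
    xml2::xml_add_child(mn, "source_bundles", p$source_bundles)
    gp <- xml2::xml_add_child(mn, "GeometryPath")
    pps <- xml2::xml_add_child(gp, "PathPointSet")
    for (i in seq_len(nrow(m$path$points))) {
      pp <- xml2::xml_add_child(pps, "PathPoint",
                                body = m$path$points$body[i])
      xml2::xml_add_child(pp, "location",
                          .num_attr(as.numeric(m$path$points[i, c("x", "y", "z")])))
    }
    if (!is.null(m$path$wraps) && length(m$path$wraps)) {
      wset <- xml2::xml_add_child(gp, "PathWrapSet")
      for (seg in names(m$path$wraps))
        xml2::xml_add_child(wset, "PathWrap", segment = seg,
                            wrap_object = m$path$wraps[[seg]])
    }
  }
  ms <- xml2::xml_add_child(mdl, "MarkerSet")
  for (mk in model$markers) {
    mkn <- xml2::xml_add_child(ms, "Marker", name = mk$name, body = mk$body)
    xml2::xml_add_child(mkn, "location", .num_attr(mk$loc))
    xml2::xml_add_child(mkn, "weight", .num_attr(mk$weight))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @keywords internal
.xml_child_num <- function(node, name) {
  ch <- xml2::xml_find_first(node, name)
  if (inherits(ch, "xml_missing")) stop(sprintf("model file: missing <%s>", name))
  .parse_nums(xml2::xml_text(ch))
}

#' Read a shoulder model from the XML model subset
#'
#' Inverse of [write_model()]. Malformed XML raises a parse error with the
#' line number (from the XML parser); invalid muscle parameters (e.g.
#' negative maximum isometric force) raise a validation error naming the
#' muscle. Elements outside the documented subset are reported with a
#' warning and skipped.
#'
#' @param path file path.
#' @return a [shoulder_model()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file does not exist: ", path)
  doc <- xml2::read_xml(path) # xml2 raises parse errors with line numbers
  mdl <- xml2::xml_find_first(doc, "//Model")
  if (inherits(mdl, "xml_missing")) stop("model file: no <Model> element")
  known_top <- c("gravity", "hand_mass", "hand_point", "BodySet", "JointSet",
                 "CoordinateSet", "WrapObjectSet", "ForceSet", "MarkerSet")
  extra <- setdiff(xml2::xml_name(xml2::xml_children(mdl)), known_top)
  if (length(extra))
    warning("model file: skipping unsupported element(s): ",
            paste(unique(extra), collapse = ", "))
  gravity <- .xml_child_num(mdl, "gravity")
  hand_mass <- .xml_child_num(mdl, "hand_mass")
  hand_point <- NULL
  hp <- xml2::xml_find_first(mdl, "hand_point")
  if (!inherits(hp, "xml_missing"))
    hand_point <- list(body = xml2::xml_attr(hp, "body"),
                       loc = .xml_child_num(hp, "location"))

  bodies <- list()
  for (bn in xml2::xml_find_all(mdl, "BodySet/Body")) {
    nm <- xml2::xml_attr(bn, "name")
    bodies[[nm]] <- body_segment(nm, .xml_child_num(bn, "mass"),
                                 .xml_child_num(bn, "mass_center"),
                                 matrix(.xml_child_num(bn, "inertia"), 3, 3))
  }
  joints <- list()
  for (jn in xml2::xml_find_all(mdl, "JointSet/Joint")) {
    type <- xml2::xml_attr(jn, "type")
    co <- trimws(xml2::xml_text(xml2::xml_find_first(jn, "coordinates")))
    params <- list()
    if (type == "hinge") params$axis <- .xml_child_num(jn, "axis")
    if (type == "ellipsoid") params$radii <- .xml_child_num(jn, "radii")
    if (type == "aim")
      params <- list(
        target_body = xml2::xml_text(xml2::xml_find_first(jn, "target_body")),
        target_point = .xml_child_num(jn, "target_point"),
        aim_ref = .xml_child_num(jn, "aim_ref"))
    joints[[length(joints) + 1]] <- list(
      name = xml2::xml_attr(jn, "name"), type = type,
      parent = xml2::xml_attr(jn, "parent"),
      child = xml2::xml_attr(jn, "child"),
      parent_offset = matrix(.xml_child_num(jn, "parent_offset"), 4, 4),
      coords = if (nzchar(co)) strsplit(co, "\\s+")[[1]] else character(0),
      params = params)
  }
  coords <- list()
  for (cn in xml2::xml_find_all(mdl, "CoordinateSet/Coordinate")) {
    nm <- xml2::xml_attr(cn, "name")
    coords[[nm]] <- model_coordinate(nm, .xml_child_num(cn, "default_value"),
                                     .xml_child_num(cn, "range"))
  }
  wraps <- list()
  for (wn in xml2::xml_find_all(mdl, "WrapObjectSet/WrapObject")) {
    nm <- xml2::xml_attr(wn, "name")
    wraps[[nm]] <- wrap_surface(nm, xml2::xml_attr(wn, "kind"),
                                xml2::xml_attr(wn, "body"),
                                matrix(.xml_child_num(wn, "xform"), 4, 4),
                                .xml_child_num(wn, "dimensions"))
  }
  muscles <- list()
  for (mn in xml2::xml_find_all(mdl, "ForceSet/Muscle")) {
    nm <- xml2::xml_attr(mn, "name")
    f_max <- .xml_child_num(mn, "max_isometric_force")
    params <- tryCatch(
      muscle_parameters(nm,
                        xml2::xml_text(xml2::xml_find_first(mn, "muscle_group")),
                        f_max,
                        .xml_child_num(mn, "optimal_fiber_length"),
                        .xml_child_num(mn, "tendon_slack_length"),
                        .xml_child_num(mn, "pennation_angle"),
                        xml2::xml_text(xml2::xml_find_first(mn, "source_bundles"))),
      error = function(e) stop("model file validation: ", conditionMessage(e),
                               call. = FALSE))
    pts <- xml2::xml_find_all(mn, "GeometryPath/PathPointSet/PathPoint")
    pdf <- do.call(rbind, lapply(pts, function(pp) {
      loc <- .xml_child_num(pp, "location")
      data.frame(body = xml2::xml_attr(pp, "body"),
                 x = loc[1], y = loc[2], z = loc[3], stringsAsFactors = FALSE)
    }))
    wl <- NULL
    pw <- xml2::xml_find_all(mn, "GeometryPath/PathWrapSet/PathWrap")
    if (length(pw)) {
      wl <- stats::setNames(
        lapply(pw, function(x) xml2::xml_attr(x, "wrap_object")),
        vapply(pw, function(x) xml2::xml_attr(x, "segment"), character(1)))
    }
    muscles[[nm]] <- list(params = params, path = muscle_path(pdf, wl))
  }
  markers <- list()
  for (mkn in xml2::xml_find_all(mdl, "MarkerSet/Marker")) {
    nm <- xml2::xml_attr(mkn, "name")
    markers[[nm]] <- model_marker(nm, xml2::xml_attr(mkn, "body"),
                                  .xml_child_num(mkn, "location"),
                                  .xml_child_num(mkn, "weight"))
  }
  shoulder_model(name = xml2::xml_attr(mdl, "name"), bodies = bodies,
                 joints = joints, coordinates = coords, muscles = muscles,
                 wraps = wraps, markers = markers, gravity = gravity,
                 hand_mass = hand_mass, hand_point = hand_point)
}
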