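#' Read a root system from RSML
#'
#' Parses Root System Markup Language (XML): nested `<root>` elements with
#' polyline geometry, per-node diameter functions and per-node emergence
#' (creation) time functions. Polylines are subdivided so that no segment
#' exceeds `max_segment_length`. Child roots must attach to a polyline
#' node of their parent root; otherwise a validation error names the root.
#'
#' @param path RSML file.
#' @param max_segment_length subdivision length, cm (default Inf: keep the
#'   polyline resolution).
#' @param time_unit `"days"` (default) or `"hours"`: unit of the creation
#'   time annotations in the file.
#' @param attach_tol maximum distance (cm) between a child root's first
#'   node and its parent polyline (default 0.5).
#' @return a [root_system()].
#' @export
read_rsml <- function(path, max_segment_length = Inf, time_unit = "days",
                      attach_tol = 0.5) {
  time_unit <- match.arg(time_unit, c("days", "hours"))
  doc <- xml2::read_xml(path) # malformed XML errors here
  plants <- xml2::xml_find_all(doc, ".//plant")
  if (length(plants) == 0) stop("read_rsml(): no <plant> element in ", path)
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$next_id <- 0L
  env$next_branch <- 0L
  env$warned_time <- FALSE
  for (plant in plants) {
    for (root in xml2::xml_find_all(plant, "./root")) {
      parse_rsml_root(root, parent_nodes = NULL, parent_ids = NULL,
                      order = 0L, env = env, attach_tol = attach_tol)
    }
  }
  if (length(env$rows) == 0) stop("read_rsml(): no root polylines in ", path)
  seg <- dplyr::bind_rows(env$rows)
  if (time_unit == "hours") seg$emergence_time <- seg$emergence_time / 24
  rs <- root_system(seg)
  if (is.finite(max_segment_length)) {
    rs <- subdivide_segments(rs, max_segment_length)
  }
  rs
}

rsml_root_id <- function(root) {
  id <- xml2::xml_attr(root, "ID")
  if (is.na(id)) id <- xml2::xml_attr(root, "id")
  if (is.na(id)) id <- "<unnamed>"
  id
}

rsml_function_values <- function(root, names) {
  for (nm in names) {
    fn <- xml2::xml_find_first(
      root, sprintf("./functions/function[@name='%s']", nm)
    )
    if (!inherits(fn, "xml_missing")) {
      smp <- xml2::xml_find_all(fn, "./sample")
      val <- xml2::xml_attr(smp, "value")
      if (all(is.na(val))) val <- xml2::xml_text(smp)
      return(list(name = nm, values = as.numeric(val)))
    }
  }
  NULL
}

parse_rsml_root <- function(root, parent_nodes, parent_ids, order, env,
                            attach_tol) {
  rid <- rsml_root_id(root)
  pts <- xml2::xml_find_all(root, "./geometry/polyline/point")
  if (length(pts) < 2) {
    stop("read_rsml(): root ", rid, " has a polyline with < 2 points")
  }
  xyz <- cbind(
    as.numeric(xml2::xml_attr(pts, "x")),
    as.numeric(xml2::xml_attr(pts, "y")),
    as.numeric(xml2::xml_attr(pts, "z"))
  )
  if (anyNA(xyz)) stop("read_rsml(): root ", rid, " has non-numeric coordinates")
  diam <- rsml_function_values(root, c("diameter", "radius"))
  radius <- if (is.null(diam)) {
    rep(0.05, nrow(xyz))
  } else if (diam$name == "radius") {
    rep_len(diam$values, nrow(xyz))
  } else {
    rep_len(diam$values / 2, nrow(xyz))
  }
  etime <- rsml_function_values(
    root, c("emergence_time", "creation_time", "node_creation_time", "age")
  )
  etime <- etime$values
  if (is.null(etime)) {
    if (!env$warned_time) {
      warning("read_rsml(): no creation-time annotations; emergence times set to 0")
      env$warned_time <- TRUE
    }
    etime <- rep(0, nrow(xyz))
  } else {
    etime <- rep_len(etime, nrow(xyz))
  }
  # attachment: first node must coincide with a node of the parent polyline
  parent_seg <- NA_integer_
  if (!is.null(parent_nodes)) {
    d2 <- colSums((t(parent_nodes) - xyz[1, ])^2)
    j <- which.min(d2)
    if (sqrt(d2[j]) > attach_tol) {
      stop(
        "read_rsml(): root ", rid, " is disconnected from its parent ",
        sprintf("(nearest parent node %.3g cm away)", sqrt(d2[j]))
      )
    }
    if (is.na(parent_ids[j])) j <- 2L # base node: attach at the first tip
    parent_seg <- parent_ids[j]
    xyz[1, ] <- parent_nodes[j, ] # snap exactly onto the parent node
  }
  env$next_branch <- env$next_branch + 1L
  branch <- env$next_branch
  nseg <- nrow(xyz) - 1
  ids <- env$next_id + seq_len(nseg)
  env$next_id <- env$next_id + nseg
  env$rows[[length(env$rows) + 1L]] <- tibble::tibble(
    id = ids,
    parent_id = c(parent_seg, ids[-nseg]),
    x1 = xyz[-nrow(xyz), 1], y1 = xyz[-nrow(xyz), 2], z1 = xyz[-nrow(xyz), 3],
    x2 = xyz[-1, 1], y2 = xyz[-1, 2], z2 = xyz[-1, 3],
    radius = (radius[-nrow(xyz)] + radius[-1]) / 2,
    order = order,
    emergence_time = etime[-1],
    branch_id = branch
  )
  # node table for children of this root: a child attaches to the segment
  # whose tip is the matched node (no segment has its tip at node 1)
  node_ids <- c(NA_integer_, ids)
  for (child in xml2::xml_find_all(root, "./root")) {
    parse_rsml_root(child, xyz, node_ids, order + 1L, env, attach_tol)
  }
  invisible(NULL)
}

#' Write a root system to RSML
#'
#' Emits one `<root>` element per branch with polyline geometry and
#' per-node `diameter` and `emergence_time` functions, children nested in
#' their parent root element.
#'
#' @param rs a [root_system()].
#' @param path destination file.
#' @param time_unit unit recorded for emergence times (`"days"` or
#'   `"hours"`).
#' @return `path`, invisibly.
#' @export
write_rsml <- function(rs, path, time_unit = "days") {
  time_unit <- match.arg(time_unit, c("days", "hours"))
  tmul <- if (time_unit == "hours") 24 else 1
  seg <- tibble::as_tibble(rs)
  branches <- split(seg, seg$branch_id)
  # parent branch of each branch (NA when collar-attached)
  pbranch <- vapply(branches, function(b) {
    p <- b$parent_id[1]
    if (is.na(p)) NA_integer_ else as.integer(seg$branch_id[match(p, seg$id)])
  }, integer(1))
  names(pbranch) <- names(branches)
  doc <- xml2::xml_new_root("rsml")
  meta <- xml2::xml_add_child(doc, "metadata")
  xml2::xml_add_child(meta, "version", "1")
  xml2::xml_add_child(meta, "unit", "cm")
  xml2::xml_add_child(meta, "property-definitions")
  scene <- xml2::xml_add_child(doc, "scene")
  plant <- xml2::xml_add_child(scene, "plant")
  add_branch <- function(parent_node, bid) {
    b <- branches[[as.character(bid)]]
    rnode <- xml2::xml_add_child(parent_node, "root", ID = as.character(bid))
    geom <- xml2::xml_add_child(rnode, "geometry")
    poly <- xml2::xml_add_child(geom, "polyline")
    xs <- c(b$x1[1], b$x2)
    ys <- c(b$y1[1], b$y2)
    zs <- c(b$z1[1], b$z2)
    for (k in seq_along(xs)) {
      xml2::xml_add_child(poly, "point",
        x = format(xs[k], digits = 17),
        y = format(ys[k], digits = 17),
        z = format(zs[k], digits = 17)
      )
    }
    fns <- xml2::xml_add_child(rnode, "functions")
    dfn <- xml2::xml_add_child(fns, "function",
      name = "diameter", domain = "polyline"
    )
    dia <- 2 * c(b$radius[1], b$radius)
    for (v in dia) {
      xml2::xml_add_child(dfn, "sample", value = format(v, digits = 17))
    }
    tfn <- xml2::xml_add_child(fns, "function",
      name = "emergence_time", domain = "polyline"
    )
    et <- tmul * c(b$emergence_time[1], b$emergence_time)
    for (v in et) {
      xml2::xml_add_child(tfn, "sample", value = format(v, digits = 17))
    }
    for (cb in names(pbranch)[!is.na(pbranch) & pbranch == bid]) {
      add_branch(rnode, cb)
    }
  }
  for (bid in names(pbranch)[is.na(pbranch)]) add_branch(plant, bid)
  xml2::write_xml(doc, path)
  invisible(path)
}
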