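#' Root systems as segment networks
#'
#' A root system is a tree of straight segments rooted at the collar.
#' Each segment stores its base (proximal, collar-side) and tip (distal)
#' coordinates, radius, branching order (0 = main axis) and emergence time
#' (days after planting). Segments are ordered so parents precede children.
#'
#' @param segments a data frame with columns `id`, `parent_id` (NA for
#'   collar-attached segments), `x1,y1,z1` (base), `x2,y2,z2` (tip),
#'   `radius` (cm), `order` (integer >= 0), `emergence_time` (d) and
#'   optionally `branch_id` (grouping of segments into polylines, used by
#'   the RSML writer).
#' @param collar_position 3-vector, cm; defaults to the base of the first
#'   collar-attached segment.
#' @param validate check tree invariants (default TRUE).
#' @return an object of class `root_system`: a tibble of segments with a
#'   `collar_position` attribute. Column `length` is (re)computed.
#' @export
root_system <- function(segments, collar_position = NULL, validate = TRUE) {
  seg <- tibble::as_tibble(segments)
  need <- c("id", "parent_id", "x1", "y1", "z1", "x2", "y2", "z2",
            "radius", "order", "emergence_time")
  miss <- setdiff(need, names(seg))
  if (length(miss) > 0) {
    stop("root_system(): missing columns: ", paste(miss, collapse = ", "))
  }
  if (!"branch_id" %in% names(seg)) seg$branch_id <- 1L
  seg$length <- sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2 +
                       (seg$z2 - seg$z1)^2)
  if (is.null(collar_position)) {
    first <- which(is.na(seg$parent_id))[1]
    if (is.na(first)) stop("root_system(): no collar-attached segment")
    collar_position <- c(seg$x1[first], seg$y1[first], seg$z1[first])
  }
  if (validate) validate_root_system(seg, collar_position)
  structure(seg,
    collar_position = collar_position,
    class = c("root_system", class(seg))
  )
}

validate_root_system <- function(seg, collar_position) {
  if (anyDuplicated(seg$id)) stop("root_system(): duplicated segment ids")
  if (any(seg$length <= 0)) stop("root_system(): zero-length segment")
  if (any(seg$radius <= 0)) stop("root_system(): non-positive radius")
  if (any(seg$order < 0)) stop("root_system(): negative branching order")
  pos <- match(seg$parent_id, seg$id)
  orphan <- !is.na(seg$parent_id) & is.na(pos)
  if (any(orphan)) {
    stop(
      "root_system(): disconnected root segment(s), no such parent: id ",
      paste(seg$id[orphan], collapse = ", ")
    )
  }
  if (any(pos >= seq_len(nrow(seg)), na.rm = TRUE)) {
    stop("root_system(): segments must be sorted parents-first")
  }
  # base must coincide with parent's tip (collar for parent-less segments)
  px <- ifelse(is.na(pos), collar_position[1], seg$x2[pos])
  py <- ifelse(is.na(pos), collar_position[2], seg$y2[pos])
  pz <- ifelse(is.na(pos), collar_position[3], seg$z2[pos])
  gap <- sqrt((seg$x1 - px)^2 + (seg$y1 - py)^2 + (seg$z1 - pz)^2)
  if (any(gap > 1e-6)) {
    stop(
      "root_system(): segment base detached from parent tip: id ",
      paste(seg$id[gap > 1e-6], collapse = ", ")
    )
  }
  invisible(TRUE)
}

#' @export
print.root_system <- function(x, ...) {
  cat(sprintf(
    "<root_system> %d segments, %d branches, orders %s, total length %.3g cm\n",
    nrow(x), length(unique(x$branch_id)),
    paste(range(x$order), collapse = "-"), sum(x$length)
  ))
  invisible(x)
}

#' Collar position of a root system
#' @param rs a [root_system()].
#' @return numeric 3-vector, cm.
#' @export
collar_position <- function(rs) attr(rs, "collar_position")

#' Alive segments at a time
#'
#' @param rs a [root_system()].
#' @param t days after planting.
#' @return the subset of segments with `emergence_time <= t` (still a
#'   `root_system`).
#' @export
alive_segments <- function(rs, t) {
  keep <- rs$emergence_time <= t
  out <- rs[keep, ]
  structure(out,
    collar_position = collar_position(rs),
    class = class(rs)
  )
}

#' Total alive root length
#' @inheritParams alive_segments
#' @return length, cm.
#' @export
total_root_length <- function(rs, t = Inf) sum(alive_segments(rs, t)$length)

#' Maximum rooting depth at a time
#' @inheritParams alive_segments
#' @return depth below the surface, cm (positive; 0 if nothing alive).
#' @export
rooting_depth <- function(rs, t = Inf) {
  al <- alive_segments(rs, t)
  if (nrow(al) == 0) return(0)
  max(0, -min(al$z2, al$z1))
}

#' Subdivide segments to a maximum length
#'
#' Splits every segment into equal parts no longer than `max_len`,
#' preserving geometry, radius, order, branch identity and emergence time
#' (all parts of a segment emerge together).
#'
#' @param rs a [root_system()].
#' @param max_len maximum segment length, cm.
#' @return a new `root_system` with `length <= max_len` everywhere.
#' @export
subdivide_segments <- function(rs, max_len) {
  stopifnot(max_len > 0)
  if (all(rs$length <= max_len + 1e-12)) return(rs)
  nparts <- pmax(1L, as.integer(ceiling(rs$length / max_len - 1e-12)))
  n <- nrow(rs)
  rows <- vector("list", n)
  next_id <- max(rs$id) + 1L
  # id of the part that children of original segment i must attach to
  tip_id <- rs$id
  for (i in seq_len(n)) {
    k <- nparts[i]
    if (k == 1L) {
      rows[[i]] <- rs[i, ]
      next
    }
    f <- seq(0, 1, length.out = k + 1)
    ids <- c(rs$id[i], seq.int(next_id, length.out = k - 1L))
    next_id <- next_id + k - 1L
    part <- rs[rep(i, k), ]
    part$id <- ids
    part$parent_id <- c(rs$parent_id[i], ids[-k])
    part$x1 <- rs$x1[i] + f[-(k + 1)] * (rs$x2[i] - rs$x1[i])
    part$y1 <- rs$y1[i] + f[-(k + 1)] * (rs$y2[i] - rs$y1[i])
    part$z1 <- rs$z1[i] + f[-(k + 1)] * (rs$z2[i] - rs$z1[i])
    part$x2 <- rs$x1[i] + f[-1] * (rs$x2[i] - rs$x1[i])
    part$y2 <- rs$y1[i] + f[-1] * (rs$y2[i] - rs$y1[i])
    part$z2 <- rs$z1[i] + f[-1] * (rs$z2[i] - rs$z1[i])
    rows[[i]] <- part
    tip_id[i] <- ids[k]
  }
  out <- dplyr::bind_rows(rows)
  # reattach children of subdivided segments to the last part
  remap <- stats::setNames(tip_id, rs$id)
  orig <- out$id %in% rs$id & !is.na(out$parent_id)
  out$parent_id[orig] <- unname(remap[as.character(out$parent_id[orig])])
  root_system(out, collar_position(rs))
}

#' Export the segment table
#'
#' @param rs a [root_system()].
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_segments_csv <- function(rs, path) {
  utils::write.csv(as.data.frame(rs)[, c(
    "id", "parent_id", "x1", "y1", "z1", "x2", "y2", "z2",
    "radius", "order", "emergence_time", "branch_id", "length"
  )], path, row.names = FALSE)
  invisible(path)
}
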