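#' Enumerate genealogical connecting paths between two individuals
#'
#' A kinship path runs from `a` upward through zero or more ancestors to a
#' single apex and then downward through zero or more descendants of the apex
#' to `b` — the standard genealogical connection (parent, grandparent,
#' sibling, uncle/aunt, cousin, ...).  Paths never descend and re-ascend, so
#' in-law chains through marriages are not connections.  All simple paths of
#' at most `max_len` parent-child edges are returned; in inbred pedigrees two
#' individuals can be connected by many distinct paths.
#'
#' @param ped a `pedigree`.
#' @param a,b individual ids, `a != b`.
#' @param max_len maximum number of edges in a path.
#' @return A list of `kinship_path` objects.  Each has elements `ids` (the
#'   individuals along the path, starting at `a` and ending at `b`), `up`
#'   (number of ascending edges) and `down`; interior individuals are
#'   `ids[-c(1, length(ids))]`.  Empty list if unconnected within `max_len`.
#' @export
connecting_paths <- function(ped, a, b, max_len = 12L) {
  stopifnot(inherits(ped, "pedigree"))
  if (identical(a, b)) mbd_error("mbdfam_malformed", "a and b must differ")
  ix <- ped_index(ped)
  if (is.na(ix$idx[a]) || is.na(ix$idx[b])) {
    mbd_error("mbdfam_malformed", "a and b must both be in the pedigree")
  }
  ai <- ix$idx[[a]]; bi <- ix$idx[[b]]
  out <- list()

  descend <- function(path, apex_at) {
    v <- path[length(path)]
    if (v == bi) {
      out[[length(out) + 1L]] <<- new_kinship_path(ped$id[path], up = apex_at - 1L)
      return(invisible())
    }
    if (length(path) - 1L >= max_len) return(invisible())
    for (k in ix$children[[v]]) {
      if (!(k %in% path)) descend(c(path, k), apex_at)
    }
    invisible()
  }

  ascend <- function(path) {
    v <- path[length(path)]
    # v is a candidate apex: try to walk down to b (or v may be b itself)
    descend(path, apex_at = length(path))
    if (length(path) - 1L >= max_len) return(invisible())
    for (p in c(ix$father[v], ix$mother[v])) {
      if (!is.na(p) && !(p %in% path)) ascend(c(path, p))
    }
    invisible()
  }

  ascend(ai)
  # drop duplicates: b may be reached while it is also an apex candidate
  keys <- vapply(out, function(p) paste(p$ids, collapse = "\r"), "")
  out <- out[!duplicated(keys)]
  out[order(vapply(out, function(p) length(p$ids), 0L),
            vapply(out, function(p) paste(p$ids, collapse = "\r"), ""))]
}

new_kinship_path <- function(ids, up) {
  structure(list(ids = ids, up = as.integer(up),
                 down = length(ids) - 1L - as.integer(up)),
            class = "kinship_path")
}

#' Label the relationship described by a kinship path
#'
#' The label depends only on the shape of the path: the number of ascending
#' edges `u` and descending edges `d`.
#'
#' @param path a `kinship_path` from [connecting_paths()].
#' @return one of `"parent-offspring"`, `"sibling"`, `"grandparent-line"`,
#'   `"uncle-aunt"`, `"cousin"`, `"other"`.
#' @export
relationship_label <- function(path) {
  if (!inherits(path, "kinship_path") || length(path$ids) < 2L ||
      path$up < 0L || path$down < 0L) {
    mbd_error("mbdfam_malformed", "not a valid kinship path")
  }
  u <- path$up; d <- path$down
  if (u + d == 1L) return("parent-offspring")
  if (u == 0L || d == 0L) return("grandparent-line")
  if (u == 1L && d == 1L) return("sibling")
  if ((u >= 2L && d == 1L) || (u == 1L && d >= 2L)) return("uncle-aunt")
  if (u == 2L && d == 2L) return("cousin")
  "other"
}

#' @export
print.kinship_path <- function(x, ...) {
  cat(sprintf("kinship path (%s, up %d / down %d): %s\n",
              relationship_label(x), x$up, x$down, paste(x$ids, collapse = " -> ")))
  invisible(x)
}
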