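#' Construct a nucleus-size time series
#'
#' @param times frame times in ns, strictly increasing.
#' @param n nucleus sizes (molecule counts of the largest ice cluster).
#' @param members optional list of per-frame member molecule-id vectors.
#' @return object of class `nucleus_series`.
#' @export
nucleus_series <- function(times, n, members = NULL) {
  if (length(times) != length(n)) stop("times and n differ in length")
  if (any(n < 0)) stop("nucleus sizes must be nonnegative")
  if (length(times) > 1L && any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), n = as.numeric(n), members = members),
            class = "nucleus_series")
}

#' @export
print.nucleus_series <- function(x, ...) {
  cat(sprintf("<nucleus_series> %d frames, t = [%g, %g] ns, n = [%g, %g]\n",
              length(x$times), min(x$times), max(x$times), min(x$n), max(x$n)))
  invisible(x)
}

#' Largest ice nucleus in a frame
#'
#' Connected components over the HEX + CUBIC molecules (interfacial and
#' liquid molecules are excluded from the nucleus) with minimum-image O-O
#' adjacency within `link_cutoff`. Ties between equal-size components are
#' broken by the lexicographically smallest member molecule id.
#'
#' @param labels an `ice_labels` result from [classify_ice()].
#' @param frame the `md_frame` the labels were computed from.
#' @param link_cutoff O-O linking cutoff in nm (default 0.35).
#' @param periodic logical length-3 axis periodicity.
#' @return list with `n` (component size, 0 when no ice-like molecules) and
#'   `members` (sorted molecule ids).
#' @export
largest_nucleus <- function(labels, frame, link_cutoff = 0.35,
                            periodic = c(TRUE, TRUE, TRUE)) {
  sel <- which(labels$label %in% c("HEX", "CUBIC"))
  if (!length(sel)) return(list(n = 0L, members = integer()))
  o_idx <- attr(labels, "o_idx")[sel]
  o <- frame$positions[o_idx, , drop = FALSE]
  molid <- labels$molid[sel]
  if (length(sel) == 1L) return(list(n = 1L, members = molid))
  dm <- pairwise_min_image(o, frame$box, periodic)
  adj <- which(dm <= link_cutoff & upper.tri(dm), arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(adj, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(sel) - igraph::vcount(g)))
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    mins <- vapply(best, function(b) min(molid[comp$membership == b]), numeric(1))
    best <- best[which.min(mins)]
  }
  members <- sort(molid[comp$membership == best])
  list(n = length(members), members = members)
}

#' Nucleus-size time series over a trajectory
#'
#' Applies [classify_ice()] and [largest_nucleus()] to every frame.
#'
#' @param trajectory an `md_trajectory`.
#' @param neighbor_cutoff,staggered_max,eclipsed_range,periodic passed to
#'   [classify_ice()].
#' @param link_cutoff passed to [largest_nucleus()].
#' @return a [nucleus_series()] with per-frame member lists.
#' @export
nucleus_timeseries <- function(trajectory, neighbor_cutoff = 0.35,
                               link_cutoff = 0.35, staggered_max = -0.8,
                               eclipsed_range = c(-0.35, 0.25),
                               periodic = c(TRUE, TRUE, TRUE)) {
  res <- lapply(trajectory$frames, function(f) {
    lab <- classify_ice(f, neighbor_cutoff, staggered_max, eclipsed_range, periodic)
    largest_nucleus(lab, f, link_cutoff, periodic)
  })
  nucleus_series(
    times = trajectory$times,
    n = vapply(res, function(r) as.numeric(r$n), numeric(1)),
    members = lapply(res, `[[`, "members")
  )
}

#' Find hexagonal rings in a hydrogen-bond graph
#'
#' Enumerates all simple six-membered cycles of the molecule-level O-O
#' hydrogen-bond graph, deduplicated up to rotation and reflection. Each ring
#' is reported starting from its smallest member id.
#'
#' @param hbond_pairs two-column matrix (or data frame) of bonded molecule
#'   id pairs, e.g. from [detect_hbonds()].
#' @return list of integer length-6 vectors (molecule ids in ring order).
#' @export
find_hexagonal_rings <- function(hbond_pairs) {
  if (is.null(hbond_pairs) || nrow(hbond_pairs) == 0L) return(list())
  pairs <- as.matrix(hbond_pairs[, 1:2, drop = FALSE])
  verts <- sort(unique(as.vector(pairs)))
  adj <- lapply(stats::setNames(vector("list", length(verts)), verts), function(x) integer())
  key <- function(v) as.character(v)
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    if (a == b) next
    adj[[key(a)]] <- union(adj[[key(a)]], b)
    adj[[key(b)]] <- union(adj[[key(b)]], a)
  }
  rings <- list()
  # canonical enumeration: cycle root = minimum member; only visit vertices
  # larger than the root; reflection removed by requiring path[2] < path[6]
  for (v0 in verts) {
    path <- integer(6)
    path[1] <- v0
    dfs <- function(depth) {
      cur <- path[depth]
      for (w in adj[[key(cur)]]) {
        if (depth == 6L) {
          if (w == v0 && path[2] < path[6]) {
            rings[[length(rings) + 1L]] <<- path
          }
        } else if (w > v0 && !(w %in% path[seq_len(depth)])) {
          path[depth + 1L] <<- w
          dfs(depth + 1L)
        }
      }
    }
    dfs(1L)
  }
  rings
}
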