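#' Canonical antipodal representative of a direction
#'
#' Orientations on the sphere are sign-ambiguous; the canonical
#' representative has positive z component, with ties broken by y > 0, then
#' x > 0. All reported orientations use this convention.
#'
#' @param v A length-3 vector or n x 3 matrix of directions.
#' @param tol Tolerance for treating a component as zero.
#' @return Directions with canonical sign, same shape as the input.
#' @export
canonical_direction <- function(v, tol = 1e-10) {
  m <- rbind(v)
  flip <- m[, 3] < -tol |
    (abs(m[, 3]) <= tol & m[, 2] < -tol) |
    (abs(m[, 3]) <= tol & abs(m[, 2]) <= tol & m[, 1] < 0)
  m[flip, ] <- -m[flip, , drop = FALSE]
  if (is.matrix(v)) m else drop(m)
}

.icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  p, 0), c(1,  p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1,  p), c(0, 1,  p), c(0, -1, -p), c(0, 1, -p),
    c( p, 0, -1), c(p, 0,  1), c(-p, 0, -1), c(-p, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

#' Icosphere sampling grid on the unit sphere
#'
#' Subdivides the regular icosahedron `subdivisions` times (each triangle
#' into four) and projects vertices to the unit sphere, giving
#' `10 * 4^s + 2` quasi-uniform directions with 1-ring neighbor lists from
#' the mesh edges. With `collapse_antipodes` the grid is reduced to one
#' canonical representative per antipodal pair (hemisphere grid), and
#' neighbor lists are remapped accordingly.
#'
#' @param subdivisions Number of subdivision rounds (0..7).
#' @param collapse_antipodes Collapse antipodal vertex pairs?
#' @return An object of class `sphere_grid` with `directions` (n x 3),
#'   `neighbors` (list of integer vectors) and `hemisphere` flag.
#' @export
icosphere <- function(subdivisions = 4, collapse_antipodes = FALSE) {
  if (subdivisions < 0) {
    .axdt_stop("axdt_invalid_argument", "subdivisions must be >= 0")
  }
  if (subdivisions > 7) {
    .axdt_stop("axdt_resource_limit",
               "subdivisions > 7 would create >327k vertices")
  }
  ico <- .icosahedron()
  v <- ico$vertices
  f <- ico$faces
  for (s in seq_len(subdivisions)) {
    midpoint <- new.env(hash = TRUE)
    vlist <- list(v)
    nv <- nrow(v)
    get_mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- midpoint[[key]]
      if (!is.null(idx)) return(idx)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- m
      midpoint[[key]] <- nv
      nv
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, cc); ca <- get_mid(cc, a)
      newf[4 * t - 3, ] <- c(a, ab, ca)
      newf[4 * t - 2, ] <- c(b, bc, ab)
      newf[4 * t - 1, ] <- c(cc, ca, bc)
      newf[4 * t, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, c(list(v), vlist[-1]))
    f <- newf
  }
  edges <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]))
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- unique(edges)
  neighbors <- vector("list", nrow(v))
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    neighbors[[i]] <- c(neighbors[[i]], j)
    neighbors[[j]] <- c(neighbors[[j]], i)
  }
  neighbors <- lapply(neighbors, function(x) sort(unique(x)))

  if (collapse_antipodes) {
    canon <- canonical_direction(v)
    key <- apply(round(canon, 9), 1, paste, collapse = ",")
    rep_idx <- match(key, key)            # representative old index per vertex
    keep <- which(rep_idx == seq_along(rep_idx))
    new_id <- match(rep_idx, keep)        # old index -> new index
    dirs <- canon[keep, , drop = FALSE]
    nb <- vector("list", length(keep))
    for (i in seq_along(rep_idx)) {
      ni <- new_id[i]
      nb[[ni]] <- c(nb[[ni]], new_id[neighbors[[i]]])
    }
    neighbors <- lapply(seq_along(nb), function(i) sort(setdiff(unique(nb[[i]]), i)))
    v <- dirs
    hemisphere <- TRUE
  } else {
    hemisphere <- FALSE
  }
  v <- v / sqrt(rowSums(v^2))
  structure(list(directions = v, neighbors = neighbors,
                 hemisphere = hemisphere),
            class = "sphere_grid")
}
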