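#' Triangulated surface mesh
#'
#' A `surf_mesh` holds the vertex coordinates and triangular faces of one
#' hemisphere template, the substrate on which all vertex-wise statistics,
#' smoothing and cluster extraction run. Coordinates are in millimetres.
#' Vertex indices are 1-based inside R; file formats keep their native
#' 0-based convention.
#'
#' @param coords numeric V x 3 matrix of vertex positions (mm).
#' @param faces integer F x 3 matrix of vertex indices (1-based).
#' @param hemisphere `"left"` or `"right"`.
#' @return An object of class `surf_mesh` with elements `coords`, `faces`,
#'   `hemisphere`, and cached counts `V` and `F`.
#' @examples
#' m <- make_icosphere(1)
#' m$V  # 42 vertices
#' @export
surf_mesh <- function(coords, faces, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(coords) != 3L) stop("coords must be a V x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be a F x 3 matrix")
  V <- nrow(coords)
  if (nrow(faces) < 1L) stop("mesh must have at least one face")
  if (any(faces < 1L) || any(faces > V)) {
    stop("face indices out of range [1, ", V, "]")
  }
  if (!all(seq_len(V) %in% faces)) {
    stop("every vertex must be referenced by at least one face")
  }
  m <- structure(
    list(coords = coords, faces = faces, hemisphere = hemisphere,
         V = V, F = nrow(faces)),
    class = "surf_mesh"
  )
  if (mesh_n_components(m) > 1L) {
    warning("mesh has more than one connected component; ",
            "clusters will never span components")
  }
  m
}

#' @export
print.surf_mesh <- function(x, ...) {
  cat(sprintf("surf_mesh: %d vertices, %d faces (%s hemisphere)\n",
              x$V, x$F, x$hemisphere))
  invisible(x)
}

#' Undirected edge list of a mesh
#'
#' Each shared face edge appears once, with `i < j`.
#'
#' @param mesh a `surf_mesh`.
#' @return two-column integer matrix of vertex index pairs.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(1L, 3L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e)
}

#' Vertex adjacency from faces
#'
#' Two vertices are adjacent iff they share a face edge. The result is
#' symmetric and irreflexive by construction.
#'
#' @param mesh a `surf_mesh`.
#' @return list of length V; element `v` holds the sorted integer neighbour
#'   indices of vertex `v`.
#' @examples
#' adj <- build_adjacency(make_icosphere(0))
#' lengths(adj)  # every icosahedron vertex has degree 5
#' @export
build_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  both <- rbind(e, e[, 2:1, drop = FALSE])
  nb <- split(both[, 2L], factor(both[, 1L], levels = seq_len(mesh$V)))
  unname(lapply(nb, function(x) sort(unique(as.integer(x)))))
}

mesh_n_components <- function(mesh) {
  g <- mesh_graph(mesh)
  igraph::count_components(g)
}

mesh_graph <- function(mesh) {
  igraph::graph_from_edgelist(mesh_edges(mesh), directed = FALSE)
}

edge_lengths <- function(mesh, edges = mesh_edges(mesh)) {
  d <- mesh$coords[edges[, 1L], , drop = FALSE] -
    mesh$coords[edges[, 2L], , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Face areas of a mesh
#'
#' @param mesh a `surf_mesh`.
#' @return numeric vector of F triangle areas (mm^2).
#' @export
face_areas <- function(mesh) {
  a <- mesh$coords[mesh$faces[, 1L], , drop = FALSE]
  b <- mesh$coords[mesh$faces[, 2L], , drop = FALSE]
  c_ <- mesh$coords[mesh$faces[, 3L], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Per-vertex tessellation area
#'
#' One third of each incident triangle's area is assigned to each of its
#' vertices, so vertex areas sum to the total surface area.
#'
#' @param mesh a `surf_mesh`.
#' @return numeric vector of V vertex areas (mm^2).
#' @export
vertex_areas <- function(mesh) {
  fa <- face_areas(mesh)
  va <- numeric(mesh$V)
  for (k in 1:3) {
    contrib <- tapply(fa, mesh$faces[, k], sum)
    idx <- as.integer(names(contrib))
    va[idx] <- va[idx] + contrib
  }
  va / 3
}

#' Hop (graph) distances from a seed vertex
#'
#' Breadth-first search distance in edges; used to grow effect disks and
#' to place overlap scenarios.
#'
#' @param adj adjacency list from [build_adjacency()].
#' @param seed seed vertex index.
#' @return integer vector of hop counts (Inf for unreachable vertices).
#' @export
hop_distances <- function(adj, seed) {
  V <- length(adj)
  dist <- rep(Inf, V)
  dist[seed] <- 0
  frontier <- seed
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Generate a subdivided icosahedral sphere mesh
#'
#' Starts from a regular icosahedron and subdivides each triangle into four
#' `n` times, projecting new vertices to the sphere. The result has
#' `10 * 4^n + 2` vertices and `20 * 4^n` faces. The default radius of
#' 50 mm gives a surface area (about 31,400 mm^2) in the range of a
#' (downsampled) cortical hemisphere model, so smoothing kernels stated in
#' millimetres behave sensibly.
#'
#' @param subdivisions non-negative integer subdivision count.
#' @param radius sphere radius in mm.
#' @param hemisphere label for the resulting mesh.
#' @return a `surf_mesh`.
#' @examples
#' m <- make_icosphere(3)
#' c(m$V, m$F)  # 642, 1280
#' @export
make_icosphere <- function(subdivisions = 3, radius = 50,
                           hemisphere = "left") {
  stopifnot(subdivisions >= 0, radius > 0)
  phi <- (1 + sqrt(5)) / 2
  coords <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    mid_env <- new.env(hash = TRUE, size = 4L * nrow(faces))
    nV <- nrow(coords)
    new_coords <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- mid_env[[key]]
      if (!is.null(idx)) return(idx)
      nV <<- nV + 1L
      new_coords[[length(new_coords) + 1L]] <<- (coords[i, ] + coords[j, ]) / 2
      mid_env[[key]] <- nV
      nV
    }
    new_faces <- matrix(0L, nrow(faces) * 4L, 3L)
    for (f in seq_len(nrow(faces))) {
      a <- faces[f, 1L]; b <- faces[f, 2L]; c_ <- faces[f, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      new_faces[(f - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    coords <- rbind(coords, do.call(rbind, new_coords))
    faces <- new_faces
  }
  coords <- coords * (radius / sqrt(rowSums(coords^2)))
  surf_mesh(coords, faces, hemisphere)
}
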