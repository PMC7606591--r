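# Tiny meshes and brute-force oracles shared across tests.

# single triangle: 3 vertices, 1 face
triangle_mesh <- function() {
  surf_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
            rbind(c(1, 2, 3)))
}

# two triangles sharing an edge (4 vertices)
quad_mesh <- function() {
  surf_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
            rbind(c(1, 2, 3), c(2, 4, 3)))
}

# O(V^2) adjacency oracle: scan all faces for shared edges
adjacency_oracle <- function(mesh) {
  V <- mesh$V
  A <- matrix(FALSE, V, V)
  for (f in seq_len(mesh$F)) {
    tri <- mesh$faces[f, ]
    for (pair in list(tri[1:2], tri[2:3], tri[c(1, 3)])) {
      A[pair[1], pair[2]] <- TRUE
      A[pair[2], pair[1]] <- TRUE
    }
  }
  lapply(seq_len(V), function(v) which(A[v, ]))
}

# recursive flood fill over an adjacency list restricted to `keep`
flood_fill_oracle <- function(adj, keep) {
  remaining <- sort(keep)
  comps <- list()
  while (length(remaining)) {
    comp <- remaining[1]
    frontier <- comp
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- intersect(setdiff(nxt, comp), remaining)
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    comp <- sort(comp)
    comps[[length(comps) + 1]] <- comp
    remaining <- setdiff(remaining, comp)
  }
  comps
}

# per-vertex exhaustive tally oracle for the overlap classification
overlap_tally_oracle <- function(ct, sa) {
  counts <- c(ct_only = 0, sa_only = 0, both = 0)
  for (v in seq_along(ct)) {
    a <- ct[v] != 0
    b <- sa[v] != 0
    if (a && b) counts["both"] <- counts["both"] + 1
    else if (a) counts["ct_only"] <- counts["ct_only"] + 1
    else if (b) counts["sa_only"] <- counts["sa_only"] + 1
  }
  counts
}

# published-table-shaped example counts used for arithmetic checks
# (ct_only / sa_only / both per hemisphere, per cluster threshold)
example_overlap_counts <- function() {
  list(
    "p<0.05" = list(
      left = c(ct_only = 10173, sa_only = 67029, both = 14951),
      right = c(ct_only = 12980, sa_only = 61442, both = 21293)),
    "p<0.01" = list(
      left = c(ct_only = 2604, sa_only = 50061, both = 4898),
      right = c(ct_only = 6756, sa_only = 44139, both = 5860)),
    "p<0.001" = list(
      left = c(ct_only = 529, sa_only = 30876, both = 552),
      right = c(ct_only = 1849, sa_only = 27977, both = 590))
  )
}

example_decomposition_counts <- function() {
  list(
    "p<0.05" = list(
      case_lt_control = list(
        left = c(cv_total = 40736, ct_only = 94, sa_only = 35529,
                 ct_and_sa = 3059),
        right = c(cv_total = 37381, ct_only = 264, sa_only = 28547,
                  ct_and_sa = 6386)),
      case_gt_control = list(
        left = c(cv_total = 0, ct_only = 0, sa_only = 0, ct_and_sa = 0),
        right = c(cv_total = 6828, ct_only = 2330, sa_only = 0,
                  ct_and_sa = 0))),
    "p<0.01" = list(
      case_lt_control = list(
        left = c(cv_total = 22445, ct_only = 67, sa_only = 19331,
                 ct_and_sa = 481),
        right = c(cv_total = 15797, ct_only = 30, sa_only = 13757,
                  ct_and_sa = 542)),
      case_gt_control = list(
        left = c(cv_total = 0, ct_only = 0, sa_only = 0, ct_and_sa = 0),
        right = c(cv_total = 1787, ct_only = 0, sa_only = 0,
                  ct_and_sa = 0))),
    "p<0.001" = list(
      case_lt_control = list(
        left = c(cv_total = 11183, ct_only = 22, sa_only = 9924,
                 ct_and_sa = 42),
        right = c(cv_total = 5429, ct_only = 0, sa_only = 4037,
                  ct_and_sa = 0)),
      case_gt_control = list(
        left = c(cv_total = 0, ct_only = 0, sa_only = 0, ct_and_sa = 0),
        right = c(cv_total = 0, ct_only = 0, sa_only = 0,
                  ct_and_sa = 0)))
  )
}

pct_of <- function(tab, hemi, measure, direction = NULL) {
  sel <- tab$hemisphere == hemi & tab$measure == measure
  if (!is.null(direction)) sel <- sel & tab$direction == direction
  tab$pct[sel]
}
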