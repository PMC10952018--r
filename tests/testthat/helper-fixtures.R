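# shared fixtures and independent oracles, all built in code

mk_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  suv_volume(values, spacing, origin)
}

mk_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  structure(
    list(values = array(as.logical(values), dim(values)),
         spacing = spacing, origin = origin),
    class = "suv_mask"
  )
}

mk_labels <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  structure(
    list(values = array(as.integer(values), dim(values)),
         spacing = spacing, origin = origin),
    class = "lesion_labels"
  )
}

random_mask <- function(dim3 = c(20, 20, 20), density = 0.3, seed = 1) {
  withr::with_seed(seed, mk_mask(array(runif(prod(dim3)) < density, dim3)))
}

sphere_phantom <- function(radius = 10, spacing = 1, peak = 5, noise = 0,
                           seed = 1) {
  n <- ceiling(2 * (radius + 3 * spacing) / spacing)
  n <- max(n, 8)
  ctr <- rep((n - 1) * spacing / 2, 3)
  make_phantom(phantom_spec(
    grid_shape = rep(n, 3), spacing = rep(spacing, 3),
    background_suv = 0, noise_sd = noise, seed = seed,
    lesions = list(lesion_sphere(center = ctr, radius = radius,
                                 peak_suv = peak))
  ))
}

# unit cube as 12 outward-oriented triangles
cube_mesh <- function() {
  v <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
    c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)
  )
  f <- rbind(
    c(1, 3, 2), c(1, 4, 3), c(5, 6, 7), c(5, 7, 8),
    c(1, 2, 6), c(1, 6, 5), c(3, 4, 8), c(3, 8, 7),
    c(1, 5, 8), c(1, 8, 4), c(2, 3, 7), c(2, 7, 6)
  )
  tri_mesh(v, f)
}

# tetrahedron (0,0,0),(1,0,0),(0,1,0),(0,0,1), outward orientation
tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  tri_mesh(v, f)
}

# independent connected-component oracle: graph BFS via igraph
oracle_label <- function(mask, connectivity) {
  d <- dim(mask$values)
  fg <- which(mask$values)
  if (length(fg) == 0) return(integer(0))
  arr <- which(mask$values, arr.ind = TRUE)
  id_of <- integer(prod(d))
  id_of[fg] <- seq_along(fg)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  m <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[m <= c(`6` = 1, `18` = 2, `26` = 3)[as.character(connectivity)], ]
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    nx <- arr[, 1] + offs$dx[r]
    ny <- arr[, 2] + offs$dy[r]
    nz <- arr[, 3] + offs$dz[r]
    ok <- nx >= 1 & ny >= 1 & nz >= 1 & nx <= d[1] & ny <= d[2] & nz <= d[3]
    lin <- nx[ok] + d[1] * (ny[ok] - 1) + d[1] * d[2] * (nz[ok] - 1)
    nb <- id_of[lin]
    src <- which(ok)[nb > 0]
    edges <- rbind(edges, cbind(src, nb[nb > 0]))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(fg) - igraph::vcount(g)))
  igraph::components(g)$membership
}

# partitions equal up to relabelling
same_partition <- function(l1, l2) {
  stopifnot(length(l1) == length(l2))
  tab <- table(l1, l2)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# explicit Cox partial log-likelihood (no ties), one covariate
cox_partial_loglik <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# two-stage grid maximization of the partial likelihood
cox_grid_mle <- function(time, event, x, lo = -4, hi = 4) {
  g1 <- seq(lo, hi, by = 1e-3)
  ll1 <- vapply(g1, cox_partial_loglik, 0, time = time, event = event, x = x)
  b1 <- g1[which.max(ll1)]
  g2 <- seq(b1 - 2e-3, b1 + 2e-3, by = 1e-6)
  ll2 <- vapply(g2, cox_partial_loglik, 0, time = time, event = event, x = x)
  g2[which.max(ll2)]
}
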