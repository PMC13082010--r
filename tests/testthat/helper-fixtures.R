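# Frozen closed-form reference values, computed with 30-digit
# arbitrary-precision arithmetic from the idealized IR signal expressions
# before the implementation was written.
REF <- list(
  flair_wm   = 0.183428049212704,  # t1 850, t2 70, pd 0.7, FLAIR defaults
  dir_wm     = 0.0214106024886447, # same tissue, DIR defaults
  dir_gm     = 0.0799376579107044, # t1 1300, t2 90, pd 0.85
  fd_wm      = 0.883275199291812,  # t1 850, t2 70
  fd_gm      = 0.686625199437294,  # t1 1300, t2 90
  fd_wm_demy = 0.825279572398809   # t1 950, t2 80 (demyelination-like)
)

random_tissue <- function(n) {
  data.frame(t1 = runif(n, 300, 4500),
             t2 = runif(n, 30, 1800),
             pd = runif(n, 0.05, 1))
}

# small uniform-tissue map set for pipeline tests
uniform_maps <- function(dims = c(4, 4, 4), t1 = 850, t2 = 70, pd = 0.7,
                         voxel_size = c(1, 1, 1)) {
  quantitative_maps(array(t1, dims), array(t2, dims), array(pd, dims),
                    voxel_size = voxel_size)
}

# neighbour offsets built independently of the package internals
connectivity_offsets_for_test <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  if (connectivity == 18) g <- g[rowSums(abs(g)) <= 2, , drop = FALSE]
  g
}

# independent BFS flood-fill connected-components oracle
floodfill_components <- function(supra, offsets) {
  dims <- dim(supra)
  vox <- which(supra)
  comp <- integer(length(vox))
  names(comp) <- vox
  lab <- 0L
  idx_of <- function(ijk) ((ijk[, 3] - 1) * dims[2] + (ijk[, 2] - 1)) * dims[1] + ijk[, 1]
  for (v in vox) {
    key <- as.character(v)
    if (comp[key] != 0L) next
    lab <- lab + 1L
    queue <- v
    comp[key] <- lab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(cur, dims)
      nb <- sweep(offsets, 2, as.integer(ijk), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
        nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- idx_of(nb)
      lin <- lin[supra[lin]]
      for (w in lin) {
        k <- as.character(w)
        if (comp[k] == 0L) {
          comp[k] <- lab
          queue <- c(queue, w)
        }
      }
    }
  }
  split(as.integer(names(comp)), comp)
}
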