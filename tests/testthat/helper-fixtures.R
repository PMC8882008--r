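# shared fixture builders; everything is generated in code at test time

random_map <- function(dims = c(8, 8, 8), voxel_size = c(2, 2, 2),
                       seed = NULL, space = "native") {
  if (!is.null(seed)) set.seed(seed)
  parametric_map(array(rnorm(prod(dims)), dims), voxel_size = voxel_size,
                 space = space)
}

all_true_mask <- function(template) {
  parametric_map(array(1, dim(template$values)),
                 voxel_size = template$voxel_size,
                 affine = template$affine, space = template$space)
}

# small planted-signal blocks for direct PLS tests (no volumes involved)
planted_blocks <- function(n = 40, v = 60, b = 5, effect = 1,
                           noise_sd = 1, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  loadings <- seq(-1, 1, length.out = b)
  salience <- rnorm(v)
  salience <- salience / sqrt(sum(salience^2))
  X <- effect * outer(z, salience) + matrix(rnorm(n * v, sd = noise_sd), n, v)
  Y <- outer(z, loadings) + matrix(rnorm(n * b), n, b)
  colnames(Y) <- paste0("beh", seq_len(b))
  list(X = X, Y = Y, z = z, salience = salience, loadings = loadings)
}

# independent connected-components oracle built on igraph
igraph_components <- function(mask, connectivity = 26) {
  idx <- which(mask)
  if (!length(idx)) return(list())
  dims <- dim(mask)
  coords <- arrayInd(idx, dims)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  lookup <- stats::setNames(seq_along(idx), key(coords))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  edges <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    hit <- lookup[key(nb[ok, , drop = FALSE])]
    from <- which(ok)[!is.na(hit)]
    to <- hit[!is.na(hit)]
    edges <- c(edges, rbind(from, to))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  lapply(seq_len(comp$no), function(cc) sort(idx[comp$membership == cc]))
}
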