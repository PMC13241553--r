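# Shared fixtures: small phantoms and brute-force reference
# implementations used as independent oracles.

# a quick phantom spec small enough for unit tests (dims divisible by 8)
tiny_spec <- function(seed = 1L, shape = c(32L, 32L, 16L), ...) {
  phantom_spec(shape = shape, chiasm_halfwidth_mm = 3.2,
               tract_length_mm = 7, seed = seed, ...)
}

random_mask <- function(dim3, p = 0.2) {
  array(stats::runif(prod(dim3)) < p, dim = dim3)
}

# surface voxels by explicit 6-neighbour check (image edge = outside)
brute_surface <- function(m) {
  d <- dim(m)
  out <- array(FALSE, d)
  offs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (i in which(m)) {
    v <- arrayInd(i, d)
    for (o in offs) {
      w <- v + o
      if (any(w < 1) || any(w > d) || !m[w[1], w[2], w[3]]) {
        out[i] <- TRUE
        break
      }
    }
  }
  out
}

# all-pairs directed surface distances in mm (rows: A surface voxels)
brute_surface_dists <- function(a, b, spacing) {
  sa <- which(brute_surface(a), arr.ind = TRUE)
  sb <- which(brute_surface(b), arr.ind = TRUE)
  pa <- sweep(sa, 2, spacing, "*")
  pb <- sweep(sb, 2, spacing, "*")
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2 +
    outer(pa[, 3], pb[, 3], "-")^2
  list(dab = sqrt(apply(d2, 1, min)), dba = sqrt(apply(d2, 2, min)))
}

# brute-force overlap metrics by explicit voxel loops
brute_overlap <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0; uni <- 0
  for (i in seq_along(a)) {
    if (a[i]) na <- na + 1
    if (b[i]) nb <- nb + 1
    if (a[i] && b[i]) inter <- inter + 1
    if (a[i] || b[i]) uni <- uni + 1
  }
  list(dsc = if (na + nb == 0) 1 else 2 * inter / (na + nb),
       jaccard = if (uni == 0) 1 else inter / uni,
       precision = if (na == 0) 0 else inter / na,
       recall = if (nb == 0) 0 else inter / nb,
       vs = if (na + nb == 0) 1 else 1 - abs(na - nb) / (na + nb))
}

# largest connected component sizes by flood fill (R reference)
brute_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & (connectivity == 26 | (connectivity == 18 & m <= 2) |
                          (connectivity == 6 & m == 1)), , drop = FALSE]
  nxt <- 0L
  for (i in which(mask)) {
    if (lab[i] != 0L) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      v <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        w <- v + offs[r, ]
        if (any(w < 1) || any(w > d)) next
        j <- w[1] + d[1] * (w[2] - 1 + d[2] * (w[3] - 1))
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# random multiclass label map with the standard scheme
random_labelmap <- function(dim3, k = 9L, p = 0.3) {
  data <- array(0L, dim3)
  sel <- stats::runif(prod(dim3)) < p
  data[sel] <- sample.int(k, sum(sel), replace = TRUE)
  avp_labelmap(data, spacing = c(1, 1, 1))
}
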