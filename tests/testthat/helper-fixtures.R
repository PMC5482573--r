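# Small fixtures shared across the suite; everything is generated in code.

rand_map <- function(n, voxel = 2, seed = 1) {
  set.seed(seed)
  density_map(array(rnorm(n^3), c(n, n, n)), voxel)
}

# compact blob phantom for cheap tests; geometry scales with the voxel size
# so the blobs stay well sampled (sigma >= 1.25 voxels) at any spacing
tiny_phantom <- function(box = 24, voxel = 2) {
  phantom_spec(centers = voxel * rbind(c(3, 0, 2), c(-2, 3, -1), c(1, -3, 3)),
               sigmas = voxel * c(1.5, 1.3, 1.3), weights = c(1, 0.8, 0.7),
               gap_blob = list(center = voxel * c(0, 2, 4),
                               sigma = 1.25 * voxel, weight = 0.8),
               symmetry_order = 3, box_size = box, voxel_size = voxel)
}

# independent real-space constrained-correlation oracle
cc_oracle <- function(a, b, W) {
  n3 <- length(W)
  fa <- Re(fft(fft(a$data) * W, inverse = TRUE)) / n3
  fb <- Re(fft(fft(b$data) * W, inverse = TRUE)) / n3
  sum(fa * fb) / sqrt(sum(fa^2) * sum(fb^2))
}

# brute-force greedy dedup oracle (O(n^2))
dedup_oracle <- function(table, min_distance) {
  pos <- cbind(table$x + table$sx, table$y + table$sy, table$z + table$sz)
  cc <- if (is.null(table$cc)) rep(0, nrow(table)) else table$cc
  ord <- order(-cc, seq_len(nrow(table)))
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept)
      if (sqrt(sum((pos[i, ] - pos[j, ])^2)) < min_distance) { ok <- FALSE; break }
    if (ok) kept <- c(kept, i)
  }
  table[sort(kept), , drop = FALSE]
}

# recursive flood-fill labelling oracle for 3D masks
floodfill_oracle <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ]
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      ijk <- arrayInd(v, d)
      for (r in seq_len(nrow(offs))) {
        nb <- ijk + offs[r, ]
        if (any(nb < 1) || any(nb > d)) next
        li <- nb[1] + d[1] * (nb[2] - 1) + d[1] * d[2] * (nb[3] - 1)
        if (mask[li] && lab[li] == 0L) { lab[li] <- cur; stack <- c(stack, li) }
      }
    }
  }
  lab
}
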