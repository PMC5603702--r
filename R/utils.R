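# Integer in-plane translation of a 3D volume with zero fill.
shift_volume <- function(vol, dx, dy) {
  dx <- as.integer(round(dx)); dy <- as.integer(round(dy))
  if (dx == 0L && dy == 0L) return(vol)
  d <- dim(vol)
  out <- array(0, d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2])
  src_x <- xs - dx; src_y <- ys - dy
  ok_x <- src_x >= 1L & src_x <= d[1]
  ok_y <- src_y >= 1L & src_y <= d[2]
  out[xs[ok_x], ys[ok_y], ] <- vol[src_x[ok_x], src_y[ok_y], , drop = FALSE]
  out
}

# Estimate the integer in-plane shift that maps `ref` onto `mov` by the
# peak of the circular cross-correlation of slice-summed images.
estimate_shift_2d <- function(ref, mov) {
  a <- apply(ref, c(1, 2), sum)
  b <- apply(mov, c(1, 2), sum)
  a <- a - mean(a); b <- b - mean(b)
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
  peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  d <- dim(a)
  wrap <- function(k, n) { s <- k - 1L; if (s > n / 2) s - n else s }
  c(wrap(peak[1], d[1]), wrap(peak[2], d[2]))
}

# 3D connected-component labelling, 26-connectivity, vectorized frontier
# expansion (breadth-first over whole frontiers rather than single voxels).
label_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  pos <- array(as.logical(mask), d)
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  current <- 0L
  repeat {
    seed <- which(pos & lab == 0L)
    if (!length(seed)) break
    current <- current + 1L
    frontier <- seed[1L]
    lab[frontier] <- current
    while (length(frontier)) {
      co <- arrayInd(frontier, d)
      cand <- do.call(rbind, lapply(seq_len(nrow(nb)), function(k)
        sweep(co, 2, nb[k, ], `+`)))
      keep <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
              cand[, 2] >= 1 & cand[, 2] <= d[2] &
              cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[keep, , drop = FALSE]
      lin <- unique(cand[, 1] + d[1] * (cand[, 2] - 1L) +
                      d[1] * d[2] * (cand[, 3] - 1L))
      frontier <- lin[pos[lin] & lab[lin] == 0L]
      lab[frontier] <- current
    }
  }
  lab
}
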