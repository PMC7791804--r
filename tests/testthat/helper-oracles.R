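# independent brute-force oracle for similarity maps: explicit symmetric
# padding by block mirroring, then a double loop of patch histograms
naive_similarity <- function(qmap, h_model, k) {
  r <- (k - 1) %/% 2
  top <- qmap[r:1, , drop = FALSE]
  bot <- qmap[nrow(qmap):(nrow(qmap) - r + 1), , drop = FALSE]
  pad <- rbind(top, qmap, bot)
  left <- pad[, r:1, drop = FALSE]
  right <- pad[, ncol(pad):(ncol(pad) - r + 1), drop = FALSE]
  pad <- cbind(left, pad, right)
  out <- matrix(NA_real_, nrow(qmap), ncol(qmap))
  for (i in seq_len(nrow(qmap))) for (j in seq_len(ncol(qmap))) {
    patch <- as.vector(pad[i:(i + k - 1), j:(j + k - 1)])
    hp <- vapply(seq_along(h_model) - 1L,
                 function(l) sum(patch == l), numeric(1)) / length(patch)
    out[i, j] <- sum(pmin(h_model, hp))
  }
  out
}
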