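# shared helpers: hand-built models and independent brute-force oracles

# minimal backbone_model with one CA atom per residue at given coordinates
make_ca_model <- function(coords, seq = NULL, model = 1L) {
  n <- nrow(coords)
  codes <- if (is.null(seq)) rep("A", n) else strsplit(seq, "")[[1]]
  atoms <- data.frame(chain = "A", resno = seq_len(n), ires = seq_len(n),
                      code = codes, atom = "CA", element = "C",
                      x = coords[, 1], y = coords[, 2], z = coords[, 3])
  residues <- data.frame(ires = seq_len(n), chain = "A",
                         resno = seq_len(n), code = codes,
                         gap_before = c(TRUE, rep(FALSE, n - 1L)),
                         complete = FALSE)
  structure(list(atoms = atoms, residues = residues, model = model),
            class = "backbone_model")
}

# brute-force residue-pair contact count (independent of count_contacts)
brute_contacts <- function(coords, cutoff = 8, exclusion = 2) {
  n <- nrow(coords)
  total <- 0L
  per <- integer(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j - i <= exclusion) next
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (r < cutoff) {
        total <- total + 1L
        per[i] <- per[i] + 1L
        per[j] <- per[j] + 1L
      }
    }
  }
  list(total = total, per_residue = per)
}

# direct -sum p log p oracle
entropy_oracle <- function(p) {
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

# rigid-body transform of an n x 3 coordinate matrix
rigid_transform <- function(coords, angles = c(0.3, -1.1, 2.0),
                            shift = c(5, -3, 11)) {
  rx <- matrix(c(1, 0, 0,
                 0, cos(angles[1]), -sin(angles[1]),
                 0, sin(angles[1]), cos(angles[1])), 3, byrow = TRUE)
  ry <- matrix(c(cos(angles[2]), 0, sin(angles[2]),
                 0, 1, 0,
                 -sin(angles[2]), 0, cos(angles[2])), 3, byrow = TRUE)
  rz <- matrix(c(cos(angles[3]), -sin(angles[3]), 0,
                 sin(angles[3]), cos(angles[3]), 0,
                 0, 0, 1), 3, byrow = TRUE)
  sweep(coords %*% t(rz %*% ry %*% rx), 2, shift, "+")
}

# apply a rigid transform to every atom of a backbone_model
transform_model <- function(model, ...) {
  xyz <- rigid_transform(cbind(model$atoms$x, model$atoms$y,
                               model$atoms$z), ...)
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}
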