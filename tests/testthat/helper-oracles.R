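# Independent oracles and tiny text fixtures shared across tests.

glyFixturePDB <- function() c(
  "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00  0.00           C",
  "ATOM      4  O   GLY A   1       1.251   2.390   0.000  1.00  0.00           O",
  "END")

calciumFixturePDB <- function() c(
  glyFixturePDB()[1:4],
  "HETATM    5 CA    CA A 201      10.000  10.000  10.000  1.00  0.00          CA",
  "END")

# exhaustive all-atom-pairs ion-pair detector, written independently of the
# package's vectorized implementation
bruteIonPairs <- function(structure, saltCutoff = 4, longCutoff = 8) {
  a <- atoms(structure)
  rt <- residueTable(structure)
  acidNames <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  baseNames <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
  acids <- rt[rt$resid %in% names(acidNames), , drop = FALSE]
  bases <- rt[rt$resid %in% names(baseNames), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(acids))) for (j in seq_len(nrow(bases))) {
    ai <- a[a$chain == acids$chain[i] & a$resno == acids$resno[i] &
              a$ins == acids$ins[i] &
              a$elety %in% acidNames[[acids$resid[i]]], , drop = FALSE]
    bj <- a[a$chain == bases$chain[j] & a$resno == bases$resno[j] &
              a$ins == bases$ins[j] &
              a$elety %in% baseNames[[bases$resid[j]]], , drop = FALSE]
    if (nrow(ai) == 0L || nrow(bj) == 0L) next
    md <- Inf
    for (p in seq_len(nrow(ai))) for (q in seq_len(nrow(bj))) {
      d <- sqrt((ai$x[p] - bj$x[q])^2 + (ai$y[p] - bj$y[q])^2 +
                  (ai$z[p] - bj$z[q])^2)
      if (d < md) md <- d
    }
    if (md > longCutoff) next
    out[[length(out) + 1L]] <- data.frame(
      acid_key = acids$key[i], base_key = bases$key[j], min_dist = md,
      category = if (md <= saltCutoff) "salt_bridge" else "long_range",
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(acid_key = character(),
                                      base_key = character(),
                                      min_dist = numeric(),
                                      category = character()))
  do.call(rbind, out)
}

# union-find connected components over an edge list of residue keys
unionFindComponents <- function(acid, base) {
  nodes <- unique(c(acid, base))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_along(acid)) {
    ra <- find(acid[k]); rb <- find(base[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(nodes, find, character(1))
}

# minimal pair table accepted by buildIonicNetworks
fakePairTable <- function(acid, base) {
  data.frame(acid_key = acid, base_key = base,
             acid_resno = as.integer(factor(acid,
                                            levels = unique(c(acid, base)))),
             base_resno = as.integer(factor(base,
                                            levels = unique(c(acid, base)))),
             min_dist = 3, category = "salt_bridge",
             pair_rasa = NA_real_, exposed = NA,
             acid_resid = "ASP", base_resid = "LYS",
             stringsAsFactors = FALSE)
}

randomRotationMatrix <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# canonical Type I turn hosted in a 6-residue peptide; the turn window is
# residues 2..5 and the i+1 residue (position 3) is settable
turnSpec <- function(i1 = "SER") {
  dihedralSpec(c("GLY", "ALA", i1, "GLY", "ALA", "GLY"),
               phi = c(NA, -140, -60, -90, -140, -140),
               psi = c(135, 135, -30, 0, 135, NA))
}
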