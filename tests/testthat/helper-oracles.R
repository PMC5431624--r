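# Independent oracles and small generators used across the suite.

# Marked-box oracle for phylogenetic compatibility: alleles of one locus
# across the top of a matrix, alleles of the other down the side, observed
# combinations marked. Incompatible iff one can leave a marked box and
# return to it by alternating horizontal and vertical moves through other
# marked boxes. Plain path enumeration, deliberately naive.
oracle_compatible <- function(combos) {
  combos <- unique(combos[c("a", "b")])
  n <- nrow(combos)
  if (n < 4) return(TRUE)  # a box cycle needs at least 4 boxes
  found <- FALSE
  visited <- logical(n)
  dfs <- function(cur, last_dir, start, depth) {
    if (found) return()
    for (dir in setdiff(c("h", "v"), last_dir)) {
      nb <- if (dir == "h") which(combos$b == combos$b[cur])
            else which(combos$a == combos$a[cur])
      for (x in setdiff(nb, cur)) {
        if (x == start && depth >= 3) { found <<- TRUE; return() }
        if (!visited[x]) {
          visited[x] <<- TRUE
          dfs(x, dir, start, depth + 1)
          visited[x] <<- FALSE
        }
      }
    }
  }
  for (s in seq_len(n)) {
    visited[] <- FALSE
    visited[s] <- TRUE
    dfs(s, NA_character_, s, 1)
    if (found) break
  }
  !found
}

# random two-locus genotype matrix for oracle-agreement sweeps
random_two_locus_gm <- function(n_isolates, n_alleles_j, n_alleles_k) {
  genotype_matrix(data.frame(
    locj = sample(letters[seq_len(n_alleles_j)], n_isolates, replace = TRUE),
    lock = sample(LETTERS[seq_len(n_alleles_k)], n_isolates, replace = TRUE),
    stringsAsFactors = FALSE))
}

# brute-force IA/rbarD through explicit pair loops and mismatch_distance;
# independent of the vectorised implementation
brute_ia <- function(gm) {
  m <- as.matrix(as.data.frame(gm)[, loci(gm), drop = FALSE])
  n <- nrow(m)
  pr <- utils::combn(n, 2)
  dtot <- apply(pr, 2, function(p) mismatch_distance(m[p[1], ], m[p[2], ]))
  popvar <- function(x) mean(x^2) - mean(x)^2
  vj <- apply(m, 2, function(col) {
    d <- apply(pr, 2, function(p) as.numeric(col[p[1]] != col[p[2]]))
    popvar(d)
  })
  VO <- popvar(dtot)
  VE <- sum(vj)
  s <- sqrt(vj)
  list(IA = VO / VE - 1,
       rbarD = (VO - VE) / (2 * (sum(s)^2 - sum(s^2)) / 2))
}

# founder fixture used by several clonality tests: two fully linked
# multilocus genotypes in equal numbers
two_founder_gm <- function(n_per_founder = 2) {
  genotype_matrix(data.frame(
    L1 = rep(c("A", "a"), each = n_per_founder),
    L2 = rep(c("B", "b"), each = n_per_founder),
    stringsAsFactors = FALSE))
}
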