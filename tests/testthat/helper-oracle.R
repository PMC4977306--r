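# Independent folding oracle: exhaustive enumeration of all nested
# structures (hairpin loop >= 3) with energies evaluated by loop
# decomposition straight from the fold_params() tables. Written without
# reference to the dynamic programme it checks.

.op <- fold_params()

oracle_pair_type <- function(a, b) {
  key <- paste0(chartr("T", "U", a), chartr("T", "U", b))
  if (key %in% rownames(.op$stack)) key else NA_character_
}

oracle_can_pair <- function(a, b) !is.na(oracle_pair_type(a, b))

## all nested pair sets over s[i..j] as lists of (k, l) pairs
oracle_enumerate <- function(bases, i, j, memo = new.env(parent = emptyenv())) {
  if (i > j) return(list(list()))
  key <- paste(i, j)
  if (!is.null(memo[[key]])) return(memo[[key]])
  out <- lapply(oracle_enumerate(bases, i, j - 1L, memo), identity)
  for (k in i:max(i, j - 4L)) {
    if (j - k - 1L < 3L) next
    if (!oracle_can_pair(bases[k], bases[j])) next
    left <- oracle_enumerate(bases, i, k - 1L, memo)
    inner <- oracle_enumerate(bases, k + 1L, j - 1L, memo)
    for (L in left) for (I in inner)
      out[[length(out) + 1L]] <- c(L, I, list(c(k, j)))
  }
  memo[[key]] <- out
  out
}

.op_extrap <- function(tab, n) {
  sizes <- as.integer(names(tab))
  if (n <= max(sizes)) return(unname(tab[as.character(n)]))
  unname(tab[length(tab)]) + .op$loop_extrapolation * log(n / max(sizes))
}

## energy of one structure by loop decomposition over the pair tree
oracle_energy <- function(seq, pairs) {
  if (length(pairs) == 0) return(0)
  bases <- strsplit(seq, "")[[1]]
  mat <- do.call(rbind, pairs)
  mat <- mat[order(mat[, 1]), , drop = FALSE]
  np <- nrow(mat)
  # parent of each pair: the tightest enclosing pair
  parent <- rep(NA_integer_, np)
  for (p in seq_len(np)) {
    enc <- which(mat[, 1] < mat[p, 1] & mat[, 2] > mat[p, 2])
    if (length(enc)) parent[p] <- enc[which.max(mat[enc, 1])]
  }
  partner <- rep(NA_integer_, nchar(seq))
  partner[mat[, 1]] <- mat[, 2]; partner[mat[, 2]] <- mat[, 1]
  e <- 0
  for (p in seq_len(np)) {
    i <- mat[p, 1]; j <- mat[p, 2]
    ch <- which(!is.na(parent) & parent == p)
    pt <- oracle_pair_type(bases[i], bases[j])
    if (length(ch) == 0) {
      e <- e + .op_extrap(.op$hairpin, j - i - 1L)
    } else if (length(ch) == 1) {
      k <- mat[ch, 1]; l <- mat[ch, 2]
      n1 <- k - i - 1L; n2 <- j - l - 1L
      if (n1 == 0 && n2 == 0) {
        e <- e + .op$stack[pt, oracle_pair_type(bases[k], bases[l])]
      } else if (n1 == 0 || n2 == 0) {
        e <- e + .op_extrap(.op$bulge, n1 + n2)
      } else {
        e <- e + .op_extrap(.op$internal, n1 + n2) +
          min(.op$asym[["max"]], .op$asym[["coef"]] * abs(n1 - n2))
      }
    } else {
      unpaired <- sum(is.na(partner[(i + 1L):(j - 1L)])) -
        sum(vapply(ch, function(q) {
          inside <- (mat[q, 1] + 1L):(mat[q, 2] - 1L)
          sum(is.na(partner[inside]))
        }, numeric(1)))
      e <- e + .op$multi[["a"]] + .op$multi[["b"]] * (length(ch) + 1L) +
        .op$multi[["c"]] * unpaired
    }
  }
  e
}

## brute-force MFE: minimum over every enumerated structure (empty = 0)
oracle_mfe <- function(seq) {
  seq <- chartr("U", "T", toupper(seq))
  bases <- strsplit(seq, "")[[1]]
  structs <- oracle_enumerate(bases, 1L, length(bases))
  min(vapply(structs, function(p) oracle_energy(seq, p), numeric(1)))
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
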