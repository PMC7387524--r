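# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: the matcher oracle enumerates injections
# directly, the silhouette oracle is a literal double loop, and the
# alignment oracle is a textbook affine-gap (Gotoh) dynamic program.

# exhaustive subgraph-monomorphism search by candidate enumeration
brute_force_isomorphisms <- function(pattern, target) {
  p_ids <- sort(pattern$atoms$atom_id)
  p_elem <- stats::setNames(pattern$atoms$element, pattern$atoms$atom_id)
  t_elem <- stats::setNames(target$atoms$element, target$atoms$atom_id)
  bond_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  t_bonds <- bond_key(target$bonds$from, target$bonds$to)
  cand <- lapply(p_ids, function(p) {
    target$atoms$atom_id[t_elem == p_elem[[p]]]
  })
  if (any(lengths(cand) == 0)) return(list())
  grid <- expand.grid(cand, stringsAsFactors = FALSE)
  keep <- apply(grid, 1, function(row) {
    if (anyDuplicated(row)) return(FALSE)
    names(row) <- p_ids
    for (i in seq_len(nrow(pattern$bonds))) {
      a <- row[[pattern$bonds$from[i]]]
      b <- row[[pattern$bonds$to[i]]]
      if (!bond_key(a, b) %in% t_bonds) return(FALSE)
    }
    TRUE
  })
  if (!any(keep)) return(list())
  out <- lapply(which(keep), function(r) {
    v <- as.character(unlist(grid[r, ]))
    stats::setNames(v, p_ids)
  })
  keys <- vapply(out, paste, character(1), collapse = "\r")
  out <- out[!duplicated(keys)]
  out[order(vapply(out, paste, character(1), collapse = "\r"))]
}

random_molecular_graph <- function(n_atoms, elements = c("C", "N", "O", "S"),
                                   p_edge = 0.3) {
  ids <- paste0("a", seq_len(n_atoms))
  atoms <- data.frame(atom_id = ids,
                      element = sample(elements, n_atoms, replace = TRUE))
  pairs <- utils::combn(ids, 2)
  pick <- stats::runif(ncol(pairs)) < p_edge
  bonds <- data.frame(from = pairs[1, pick], to = pairs[2, pick])
  molecular_graph(atoms, bonds)
}

# literal double-loop silhouette
silhouette_oracle <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- Inf
    for (g in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(d[i, labels == g]))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

# textbook Gotoh global alignment with affine gaps (cost open + extend * L),
# returning identity over the full alignment length
gotoh_identity <- function(sa, sb, open = 10, extend = 0.5) {
  sub <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -open - extend * i
  for (j in seq_len(m)) Y[1, j + 1] <- -open - extend * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- sub[a[i], b[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sc
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             X[i, j + 1] - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             Y[i + 1, j] - extend)
    }
  }
  # traceback
  i <- n; j <- m
  state <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  al_a <- character(0); al_b <- character(0)
  while (i > 0 || j > 0) {
    if (state == 1 && i > 0 && j > 0) {
      sc <- sub[a[i], b[j]]
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state_new <- which.max(prev)
      al_a <- c(a[i], al_a); al_b <- c(b[j], al_b)
      i <- i - 1; j <- j - 1
      state <- state_new
    } else if (state == 2 && i > 0) {
      from_m <- M[i, j + 1] - open - extend
      from_x <- X[i, j + 1] - extend
      state_new <- if (from_m >= from_x) 1 else 2
      al_a <- c(a[i], al_a); al_b <- c("-", al_b)
      i <- i - 1
      state <- state_new
    } else if (state == 3 && j > 0) {
      from_m <- M[i + 1, j] - open - extend
      from_y <- Y[i + 1, j] - extend
      state_new <- if (from_m >= from_y) 1 else 3
      al_a <- c("-", al_a); al_b <- c(b[j], al_b)
      j <- j - 1
      state <- state_new
    } else if (i > 0) {
      al_a <- c(a[i], al_a); al_b <- c("-", al_b); i <- i - 1; state <- 1
    } else {
      al_a <- c("-", al_a); al_b <- c(b[j], al_b); j <- j - 1; state <- 1
    }
  }
  sum(al_a == al_b & al_a != "-") / length(al_a)
}

# small assigned complex built by hand: one aaRS, explicit records
toy_assigned_complex <- function(aars = "AlaRS", records = NULL,
                                 id = "TOY-001_A", volume = 100,
                                 state = "pre_activation") {
  lig <- aarsfp:::synthetic_ligand_graph(aars_ligand(aars), state)
  cx <- structure_complex(
    structure_id = id, aars = aars, ligand_graph = lig,
    interactions = if (is.null(records)) interaction_records() else records,
    reaction_state = state, kingdom = "synthetic", cavity_volume = volume)
  assign_specificity_interactions(complex_set(list(cx)))
}

rec1 <- function(itype, res, nr, atoms) {
  interaction_records(itype = itype, protein_residue_type = res,
                      protein_residue_number = nr, chain_id = "A",
                      ligand_atom_ids = list(atoms))
}

random_fp <- function(len, density = 0.2) {
  aarsfp:::new_fingerprint(which(stats::runif(len) < density), len, "rnd")
}
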