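## Extended-connectivity (Morgan/circular) fingerprints from SMILES.
##
## SMILES parsing is delegated to OpenBabel (ChemmineOB); the Morgan iteration
## and the integer-mixing hash that folds circular atom environments into a
## fixed-length bit vector are implemented here. Initial atom invariants:
## (element, heavy-atom degree, total heavy bond order, ring membership).
## Identifiers are atom-order invariant, so different SMILES of the same
## molecule give the same fingerprint. Bit positions are not interchangeable
## with other toolkits' ECFPs (hash functions differ); Jaccard similarities
## and downstream models are internally consistent.

MOD31 <- 2147483647

hash_mix <- function(values) {
  h <- 17
  for (v in values) h <- (h * 1000003 + (v %% MOD31)) %% MOD31
  h
}

## Minimal molecule graph (heavy atoms only) from parsed molblock fields.
mol_graph <- function(elem, bonds) {
  n_all <- length(elem)
  heavy <- which(elem != "H")
  remap <- match(seq_len(n_all), heavy)     # old index -> heavy index or NA
  keep <- bonds[, 1] %in% heavy & bonds[, 2] %in% heavy
  bonds <- bonds[keep, , drop = FALSE]
  bonds[, 1] <- remap[bonds[, 1]]
  bonds[, 2] <- remap[bonds[, 2]]
  ## aromatic bonds come through as order 4 in some dialects; treat as 1.5
  order_num <- ifelse(bonds[, 3] == 4, 1.5, bonds[, 3])
  n <- length(heavy)
  nbr <- vector("list", n)
  bord <- vector("list", n)
  if (nrow(bonds)) for (i in seq_len(nrow(bonds))) {
    a <- bonds[i, 1]; b <- bonds[i, 2]
    nbr[[a]] <- c(nbr[[a]], b); bord[[a]] <- c(bord[[a]], order_num[i])
    nbr[[b]] <- c(nbr[[b]], a); bord[[b]] <- c(bord[[b]], order_num[i])
  }
  list(elem = elem[heavy], n = n, bonds = bonds, order = order_num,
       nbr = nbr, bord = bord)
}

## Ring membership: a bond lies on a ring iff its endpoints stay connected
## after removing it; an atom is in a ring iff one of its bonds is.
ring_atoms <- function(g) {
  in_ring <- rep(FALSE, g$n)
  if (!nrow(g$bonds)) return(in_ring)
  for (i in seq_len(nrow(g$bonds))) {
    a <- g$bonds[i, 1]; b <- g$bonds[i, 2]
    seen <- rep(FALSE, g$n); seen[a] <- TRUE
    queue <- a
    found <- FALSE
    while (length(queue) && !found) {
      v <- queue[1]; queue <- queue[-1]
      for (j in seq_along(g$nbr[[v]])) {
        w <- g$nbr[[v]][j]
        if (v == a && w == b) next            # removed bond (one direction)
        if (v == b && w == a) next
        if (!seen[w]) {
          if (w == b) { found <- TRUE; break }
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    if (found) in_ring[c(a, b)] <- TRUE
  }
  in_ring
}

element_code <- function(elem) {
  vapply(elem, function(e) sum(utf8ToInt(e) * (256 ^ (seq_len(nchar(e)) - 1))),
         0)
}

## All Morgan environment identifiers of a molecule up to `radius`.
## An atom stops emitting once its environment no longer grows (covers no new
## bonds), so e.g. methane yields exactly one identifier at any radius.
morgan_identifiers <- function(g, radius) {
  ecode <- element_code(g$elem)
  degree <- vapply(g$nbr, length, 0L)
  bsum <- vapply(g$bord, function(x) if (length(x)) sum(x) else 0, 0)
  ring <- ring_atoms(g)
  id <- vapply(seq_len(g$n), function(a) {
    hash_mix(c(0, ecode[a], degree[a], round(bsum[a] * 10), as.integer(ring[a])))
  }, 0)
  ids <- id
  ## bond set covered by each atom's current environment (as bond indices)
  bond_idx <- lapply(seq_len(g$n), function(a) integer(0))
  atom_bonds <- lapply(seq_len(g$n), function(a) {
    if (!nrow(g$bonds)) return(integer(0))
    which(g$bonds[, 1] == a | g$bonds[, 2] == a)
  })
  active <- rep(TRUE, g$n)
  if (radius >= 1) for (r in seq_len(radius)) {
    new_id <- id
    new_bonds <- bond_idx
    for (a in which(active)) {
      if (!length(g$nbr[[a]])) { active[a] <- FALSE; next }
      ## environment grows by the bonds incident to its current frontier;
      ## simple over-approximation: bonds of all atoms within distance r
      nb <- sort(unique(c(bond_idx[[a]], atom_bonds[[a]],
                          unlist(bond_idx[g$nbr[[a]]]))))
      if (length(nb) == length(bond_idx[[a]])) { active[a] <- FALSE; next }
      ## order-invariant neighbour digest
      pairs <- cbind(g$bord[[a]], id[g$nbr[[a]]])
      ord <- order(pairs[, 1], pairs[, 2])
      new_id[a] <- hash_mix(c(r, id[a], round(t(pairs[ord, , drop = FALSE]) * 10)))
      new_bonds[[a]] <- nb
      ids <- c(ids, new_id[a])
    }
    id <- new_id
    bond_idx <- new_bonds
    if (!any(active)) break
  }
  unique(ids)
}

## Syntactic screen: OpenBabel silently repairs some malformed inputs
## (e.g. an unclosed branch), so reject them up front.
smiles_syntax_ok <- function(s) {
  if (!nzchar(s) || grepl("\\s", s)) return(FALSE)
  if (grepl("[^A-Za-z0-9@+\\-\\[\\]()=#$%/\\\\.:*]", s)) return(FALSE)
  chars <- strsplit(s, "")[[1]]
  depth_p <- cumsum((chars == "(") - (chars == ")"))
  depth_b <- cumsum((chars == "[") - (chars == "]"))
  all(depth_p >= 0) && all(depth_b >= 0) &&
    depth_p[length(chars)] == 0 && depth_b[length(chars)] == 0
}

## Parse SMILES through OpenBabel into molecule graphs (one per input).
parse_smiles <- function(smiles) {
  check_that(is.character(smiles) && length(smiles) >= 1, "need SMILES strings")
  lapply(smiles, function(s) {
    if (!smiles_syntax_ok(s)) {
      stop(sprintf("cannot parse SMILES: '%s'", s), call. = FALSE)
    }
    sdf <- tryCatch(
      ChemmineOB::convertFormat("SMI", "SDF", paste0(s, " mol\n")),
      error = function(e) "")
    mol <- parse_molblock(sdf)
    if (is.null(mol) || mol$n_atoms < 1) {
      stop(sprintf("cannot parse SMILES: '%s'", s), call. = FALSE)
    }
    mol_graph(mol$elem, mol$bonds)
  })
}

## Minimal V2000 molblock reader (counts line, atom element field, bond
## triplets). Returns NULL on malformed input.
parse_molblock <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) return(NULL)
  counts <- lines[4]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || is.na(n_bonds)) return(NULL)
  if (length(lines) < 4 + n_atoms + n_bonds) return(NULL)
  elem <- trimws(substr(lines[4 + seq_len(n_atoms)], 32, 34))
  bl <- lines[4 + n_atoms + seq_len(n_bonds)]
  bonds <- if (n_bonds > 0) {
    cbind(as.integer(substr(bl, 1, 3)), as.integer(substr(bl, 4, 6)),
          as.integer(substr(bl, 7, 9)))
  } else {
    matrix(integer(0), ncol = 3)
  }
  list(n_atoms = n_atoms, elem = elem, bonds = bonds)
}

#' Extended-connectivity fingerprint of a compound
#'
#' Computes a binary Morgan/circular fingerprint from a SMILES string:
#' circular atom environments up to `radius` bonds are assigned integer
#' identifiers (initial invariants: element, heavy degree, total bond order,
#' ring membership; then iterative neighbourhood hashing) and folded modulo
#' `nbits` into a bit vector. The defaults (radius 2, 1024 bits) are the
#' standard ECFP4-style compound featurization.
#'
#' @param smiles a single SMILES string.
#' @param radius environment radius in bonds (default 2).
#' @param nbits fingerprint length (default 1024).
#' @return Object of class `compound_fingerprint`: list with `bits`
#'   (integer 0/1 vector of length `nbits`), `n_set` and `nbits`.
#' @examples
#' fp <- ecfp("CCO")
#' fp$n_set
#' @export
ecfp <- function(smiles, radius = 2L, nbits = 1024L) {
  check_that(is.character(smiles) && length(smiles) == 1L,
             "`smiles` must be a single string")
  check_that(nbits >= 1, "`nbits` must be >= 1")
  g <- parse_smiles(smiles)[[1]]
  ids <- morgan_identifiers(g, as.integer(radius))
  bits <- integer(nbits)
  bits[(ids %% nbits) + 1] <- 1L
  structure(list(bits = bits, n_set = sum(bits), nbits = as.integer(nbits)),
            class = "compound_fingerprint")
}

#' @export
print.compound_fingerprint <- function(x, ...) {
  cat(sprintf("compound_fingerprint: %d of %d bits set\n", x$n_set, x$nbits))
  invisible(x)
}

#' Fingerprint matrix for a set of compounds
#'
#' Vectorized [ecfp()]: one row per compound.
#'
#' @param smiles named character vector of SMILES.
#' @inheritParams ecfp
#' @return Integer 0/1 matrix, `length(smiles)` x `nbits`, with rownames.
#' @export
ecfp_matrix <- function(smiles, radius = 2L, nbits = 1024L) {
  graphs <- parse_smiles(smiles)
  out <- matrix(0L, nrow = length(smiles), ncol = nbits,
                dimnames = list(names(smiles), NULL))
  for (i in seq_along(smiles)) {
    ids <- morgan_identifiers(graphs[[i]], as.integer(radius))
    out[i, (ids %% nbits) + 1] <- 1L
  }
  out
}

#' Jaccard (Tanimoto) coefficient of two fingerprints
#'
#' `|a AND b| / |a OR b|`. When both fingerprints are all-zero the
#' coefficient is defined as 1 (identical emptiness).
#'
#' @param a,b `compound_fingerprint`s (or plain 0/1 vectors) of equal length.
#' @return Real in [0, 1].
#' @export
jaccard <- function(a, b) {
  av <- if (inherits(a, "compound_fingerprint")) a$bits else as.integer(a)
  bv <- if (inherits(b, "compound_fingerprint")) b$bits else as.integer(b)
  if (length(av) != length(bv)) {
    stop(sprintf("fingerprint length mismatch: %d vs %d",
                 length(av), length(bv)), call. = FALSE)
  }
  un <- sum(av | bv)
  if (un == 0) return(1)
  sum(av & bv) / un
}
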