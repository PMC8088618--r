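## Synthetic benchmark generator.
##
## Emulates the statistical structure the method assumes, at desk scale:
## community-structured weighted interaction networks (stochastic block
## model), motif-bearing random protein sequences, template-derived compound
## SMILES, and interaction labels driven by a hidden community-compatibility
## model with separate network and molecular signal channels. Motif groups
## and fingerprint-template groups are decoupled from the network
## communities for a configurable fraction of entities, so that neither
## modality alone suffices — this is what makes the integrated model's
## synergy non-trivial rather than built in.

## Enumerated SMILES template families (small valid molecules; one family
## per compound group). No attempt at realistic chemistry beyond parseable,
## structurally distinct families.
SMILES_TEMPLATES <- list(
  alkane = c("CCCC", "CCCCC", "CCCCCC", "CCCCCCC", "CC(C)C", "CC(C)CC",
             "CCC(C)C"),
  alcohol = c("CCO", "CCCO", "CCCCO", "OCCO", "CC(O)C", "CCC(O)C", "CCCCCO"),
  aromatic = c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "Cc1ccc(C)cc1",
               "c1ccc2ccccc2c1", "Cc1cccc(C)c1"),
  amine = c("CCN", "CCCN", "CCNCC", "NCCN", "CC(N)C", "CCCCN"),
  acid = c("CC(=O)O", "CCC(=O)O", "CCCC(=O)O", "OC(=O)CC(=O)O",
           "CC(C)C(=O)O"),
  ether = c("COC", "CCOC", "CCOCC", "CCCOC", "COCCOC"),
  halide = c("CCCl", "CCCCl", "CCBr", "ClCCCl", "CCCBr", "CC(Cl)C"),
  ketone = c("CC(=O)C", "CCC(=O)C", "CC(=O)CC", "CCC(=O)CC", "CCCC(=O)C"))

#' Synthetic benchmark configuration
#'
#' Defaults define the desk-scale study conditions: 60 proteins and 60
#' compounds in 4 communities each, dense within-community edges (p_in
#' = 0.3) versus sparse between (p_out = 0.02), 10-residue community motifs
#' inserted with probability 0.9 into 60-120 residue random sequences,
#' equal network and molecular label signal (alpha = beta = 2), 70% of
#' entities with motif/template group decoupled from their network
#' community (so that neither modality alone recovers the full label
#' signal — the design requirement that makes fusion informative), 600
#' candidate pairs and a 1:2 positive:negative prevalence (positive_rate
#' 1/3).
#'
#' @param n_proteins,n_compounds entity counts.
#' @param n_protein_communities,n_compound_communities community counts K, L
#'   (L at most `length(SMILES_TEMPLATES)` = 8).
#' @param p_in,p_out within/between-community edge probabilities
#'   (0 <= p_out < p_in <= 1).
#' @param motif_length residues per community motif.
#' @param motif_insert_prob probability a protein's sequence carries its
#'   motif-group motif.
#' @param seq_length length-2 integer range of sequence lengths.
#' @param alpha,beta network / molecular signal weights on the label logit.
#' @param decouple_frac fraction of entities whose motif (template) group is
#'   redrawn independently of their network community.
#' @param n_pairs number of labelled candidate pairs to draw.
#' @param positive_rate target label prevalence in (0, 1).
#' @param ppi_score_min,cci_score_min,pci_score_min channel-score floors so
#'   that the conventional 150/150/700 thresholds retain every generated
#'   edge.
#' @param seed integer seed; everything is reproducible from it.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 60L, n_compounds = 60L,
                             n_protein_communities = 4L,
                             n_compound_communities = 4L,
                             p_in = 0.3, p_out = 0.02, motif_length = 10L,
                             motif_insert_prob = 0.9,
                             seq_length = c(60L, 120L), alpha = 2, beta = 2,
                             decouple_frac = 0.7, n_pairs = 600L,
                             positive_rate = 1 / 3, ppi_score_min = 150L,
                             cci_score_min = 150L, pci_score_min = 700L,
                             seed = 1L) {
  ## p_out = p_in is allowed: it is the structure-free null configuration
  check_that(p_out >= 0 && p_out <= p_in && p_in <= 1,
             "need 0 <= p_out <= p_in <= 1")
  check_that(n_protein_communities <= n_proteins &&
             n_compound_communities <= n_compounds,
             "more communities than entities")
  check_that(n_compound_communities <= length(SMILES_TEMPLATES),
             sprintf("at most %d compound communities supported",
                     length(SMILES_TEMPLATES)))
  check_that(alpha >= 0 && beta >= 0, "alpha and beta must be >= 0")
  structure(list(n_proteins = as.integer(n_proteins),
                 n_compounds = as.integer(n_compounds),
                 n_protein_communities = as.integer(n_protein_communities),
                 n_compound_communities = as.integer(n_compound_communities),
                 p_in = p_in, p_out = p_out,
                 motif_length = as.integer(motif_length),
                 motif_insert_prob = motif_insert_prob,
                 seq_length = as.integer(seq_length), alpha = alpha,
                 beta = beta, decouple_frac = decouple_frac,
                 n_pairs = as.integer(n_pairs),
                 positive_rate = positive_rate,
                 ppi_score_min = as.integer(ppi_score_min),
                 cci_score_min = as.integer(cci_score_min),
                 pci_score_min = as.integer(pci_score_min),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

sbm_network <- function(ids, community, p_in, p_out, score_min) {
  n <- length(ids)
  from <- character(); to <- character(); sc <- integer()
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    p <- ifelse(community[js] == community[i], p_in, p_out)
    hit <- js[stats::runif(length(js)) < p]
    if (length(hit)) {
      from <- c(from, rep(ids[i], length(hit)))
      to <- c(to, ids[hit])
      sc <- c(sc, sample(score_min:1000, length(hit), replace = TRUE))
    }
  }
  interaction_network(data.frame(from = from, to = to, weight = sc / 1000,
                                 stringsAsFactors = FALSE))
}

random_sequence <- function(len) {
  paste(sample(AA_ALPHABET20, len, replace = TRUE), collapse = "")
}

#' Generate a synthetic protein-compound interaction benchmark
#'
#' Draws community-structured PPI and CCI networks, motif-bearing protein
#' sequences, template-family compound SMILES, and labelled pairs whose
#' interaction probability is `sigmoid(bias + alpha * S_net + beta * S_mol)`
#' where `S_net` / `S_mol` are +-1 entries of hidden community- and
#' motif-group compatibility matrices; `bias` is solved so the expected
#' label prevalence matches `positive_rate`. Pairs are drawn over entities
#' present in their network (so every pair is fully featurizable). Edge
#' channel scores are sampled at or above the configured floors, so the
#' conventional confidence thresholds retain every generated edge.
#'
#' @param cfg a [synthetic_config()].
#' @return List of class `dti_benchmark`: `sequences` (named character),
#'   `smiles` (named character), `ppi`, `cci` ([interaction_network()]s),
#'   `pairs` ([labeled_pairs()]), `truth` (hidden ground truth, see
#'   [ground_truth()]) and `config`.
#' @export
generate_benchmark <- function(cfg = synthetic_config()) {
  check_that(inherits(cfg, "synthetic_config"), "`cfg` must be a synthetic_config")
  if (cfg$positive_rate <= 0 || cfg$positive_rate >= 1) {
    stop("infeasible positive_rate: must be in (0, 1)", call. = FALSE)
  }
  K <- cfg$n_protein_communities
  L <- cfg$n_compound_communities
  with_seed(cfg$seed, {
    prot_ids <- sprintf("P%03d", seq_len(cfg$n_proteins))
    comp_ids <- sprintf("C%03d", seq_len(cfg$n_compounds))
    prot_comm <- sample(rep_len(seq_len(K), cfg$n_proteins))
    comp_comm <- sample(rep_len(seq_len(L), cfg$n_compounds))

    ## motif / template groups: community, decoupled for a fraction
    decouple_p <- stats::runif(cfg$n_proteins) < cfg$decouple_frac
    motif_group <- ifelse(decouple_p,
                          sample(K, cfg$n_proteins, replace = TRUE),
                          prot_comm)
    decouple_c <- stats::runif(cfg$n_compounds) < cfg$decouple_frac
    template_group <- ifelse(decouple_c,
                             sample(L, cfg$n_compounds, replace = TRUE),
                             comp_comm)

    ## networks
    ppi <- sbm_network(prot_ids, prot_comm, cfg$p_in, cfg$p_out,
                       cfg$ppi_score_min)
    cci <- sbm_network(comp_ids, comp_comm, cfg$p_in, cfg$p_out,
                       cfg$cci_score_min)

    ## sequences with community motifs
    motifs <- vapply(seq_len(K), function(k) random_sequence(cfg$motif_length),
                     "")
    lens <- sample(cfg$seq_length[1]:cfg$seq_length[2], cfg$n_proteins,
                   replace = TRUE)
    sequences <- vapply(seq_len(cfg$n_proteins), function(i) {
      s <- random_sequence(lens[i])
      if (stats::runif(1) < cfg$motif_insert_prob) {
        m <- motifs[motif_group[i]]
        pos <- sample(nchar(s) - nchar(m) + 1L, 1L)
        substr(s, pos, pos + nchar(m) - 1L) <- m
      }
      s
    }, "")
    names(sequences) <- prot_ids

    ## compound SMILES from the template family of the compound's group
    smiles <- vapply(template_group, function(t)
      sample(SMILES_TEMPLATES[[t]], 1L), "")
    names(smiles) <- comp_ids

    ## hidden compatibility matrices (+-1, balanced as draws allow)
    compat_net <- matrix(sample(c(-1, 1), K * L, replace = TRUE), K, L)
    compat_mol <- matrix(sample(c(-1, 1), K * L, replace = TRUE), K, L)

    ## candidate pairs over entities present in their network
    p_ok <- prot_ids %in% ppi$nodes
    c_ok <- comp_ids %in% cci$nodes
    pi_ok <- which(p_ok); ci_ok <- which(c_ok)
    total <- length(pi_ok) * length(ci_ok)
    n_pairs <- min(cfg$n_pairs, total)
    sel <- sample(total, n_pairs)
    pi <- pi_ok[(sel - 1) %/% length(ci_ok) + 1]
    ci <- ci_ok[(sel - 1) %% length(ci_ok) + 1]

    eta <- cfg$alpha * compat_net[cbind(prot_comm[pi], comp_comm[ci])] +
      cfg$beta * compat_mol[cbind(motif_group[pi], template_group[ci])]
    f <- function(b) mean(sigmoid(b + eta)) - cfg$positive_rate
    bias <- stats::uniroot(f, c(-50, 50))$root
    label <- as.integer(stats::runif(n_pairs) < sigmoid(bias + eta))

    pairs <- labeled_pairs(prot_ids[pi], comp_ids[ci], label)
    truth <- list(protein_community = stats::setNames(prot_comm, prot_ids),
                  compound_community = stats::setNames(comp_comm, comp_ids),
                  motif_group = stats::setNames(motif_group, prot_ids),
                  template_group = stats::setNames(template_group, comp_ids),
                  motifs = motifs,
                  compat_network = compat_net, compat_molecular = compat_mol,
                  bias = bias)
    structure(list(sequences = sequences, smiles = smiles, ppi = ppi,
                   cci = cci, pairs = pairs, truth = truth, config = cfg),
              class = "dti_benchmark")
  })
}

#' @export
print.dti_benchmark <- function(x, ...) {
  cat(sprintf(
    "dti_benchmark: %d proteins, %d compounds, PPI %d edges, CCI %d edges, %d pairs (%.1f%% positive)\n",
    length(x$sequences), length(x$smiles), n_edges(x$ppi), n_edges(x$cci),
    nrow(x$pairs), 100 * mean(x$pairs$label)))
  invisible(x)
}

#' Ground truth of a synthetic benchmark
#'
#' Exposes the hidden generator variables for diagnostics and
#' parameter-recovery tests: community assignments, motif/template groups,
#' the K x L network and molecular compatibility matrices and the solved
#' label bias.
#'
#' @param benchmark a `dti_benchmark` from [generate_benchmark()].
#' @return List with elements `protein_community`, `compound_community`,
#'   `motif_group`, `template_group`, `motifs`, `compat_network`,
#'   `compat_molecular`, `bias`.
#' @export
ground_truth <- function(benchmark) {
  check_that(inherits(benchmark, "dti_benchmark"),
             "`benchmark` must come from generate_benchmark()")
  benchmark$truth
}

#' Write a benchmark in the upstream file dialects
#'
#' Emits `ppi.tsv`, `cci.tsv` (link tables with an `experimental` /
#' `similarity` channel), `pci.tsv` (positive pairs, `experimental`
#' channel), `sequences.fasta`, `compounds.tsv`, `pairs.tsv` (all labelled
#' pairs) and `manifest.json` into `dir`.
#'
#' @param benchmark a `dti_benchmark`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_links(benchmark$ppi, file.path(dir, "ppi.tsv"),
              id_cols = c("protein1", "protein2"),
              score_channel = "experimental")
  write_links(benchmark$cci, file.path(dir, "cci.tsv"),
              id_cols = c("chemical1", "chemical2"),
              score_channel = "similarity")
  pos <- benchmark$pairs[benchmark$pairs$label == 1, , drop = FALSE]
  cfg <- benchmark$config
  pci <- data.frame(protein = pos$protein_id, chemical = pos$compound_id,
                    experimental = sample_pci_scores(nrow(pos), cfg))
  utils::write.table(pci, file.path(dir, "pci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_sequences(benchmark$sequences, file.path(dir, "sequences.fasta"))
  write_compound_table(benchmark$smiles, file.path(dir, "compounds.tsv"))
  write_pairs(benchmark$pairs, file.path(dir, "pairs.tsv"))
  write_manifest(dir, "simulate", unclass(cfg))
  invisible(dir)
}

## deterministic given the benchmark seed: scores keyed off the pair index
sample_pci_scores <- function(n, cfg) {
  if (n == 0) return(integer(0))
  with_seed(cfg$seed + 7L,
            sample(cfg$pci_score_min:1000, n, replace = TRUE))
}
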