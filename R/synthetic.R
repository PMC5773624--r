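#' Configuration for the synthetic screening benchmark
#'
#' Bundles the parameters of the seeded generator that emulates the study
#' conditions of the screen: a reference set of rigid halogenated-aromatic
#' and polycyclic "typical" binders plus a few flexible heteroaromatic
#' "atypical" binders, a diverse candidate library with planted structural
#' analogs of the references and aliphatic/small-polar decoys (plus a small
#' quota of excluded-element decoys to exercise curation), Gaussian docking
#' scores anchored at the reference mean of -112.5 kcal/mol, and noisy
#' binary activity labels.
#'
#' @param seed Integer seed; the same seed reproduces every output exactly.
#' @param n_candidates Candidate-library size (default 1000).
#' @param n_typical_refs,n_atypical_refs Reference binders per class
#'   (defaults 61 and 5, a 66-binder panel).
#' @param n_planted_analogs Planted should-hit analogs among the candidates
#'   (default 60).
#' @param n_near_decoys Borderline decoys (monocyclic aromatics with
#'   flexible substituents) that may survive initial filtration without
#'   resembling any reference binder, keeping the evaluation universe
#'   non-trivial (default 40).
#' @param n_excluded_decoys Candidates carrying excluded elements
#'   (default 5).
#' @param binder_score_mean,binder_score_sd Docking-score distribution for
#'   binder-like compounds, kcal/mol (defaults -112.5 and 13.2).
#' @param decoy_score_mean,decoy_score_sd Docking-score distribution for
#'   decoys, kcal/mol (defaults -70 and 15; clearly separated from the
#'   binder distribution but overlapping in the tails).
#' @param active_fraction_planted,active_fraction_decoy Probability that a
#'   planted analog (resp. decoy) is labeled active (defaults 0.8 and 0.1).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_candidates = 1000L,
                             n_typical_refs = 61L,
                             n_atypical_refs = 5L,
                             n_planted_analogs = 60L,
                             n_near_decoys = 40L,
                             n_excluded_decoys = 5L,
                             binder_score_mean = -112.5,
                             binder_score_sd = 13.2,
                             decoy_score_mean = -70,
                             decoy_score_sd = 15,
                             active_fraction_planted = 0.8,
                             active_fraction_decoy = 0.1) {
  stopifnot(n_candidates >= n_planted_analogs + n_near_decoys +
              n_excluded_decoys,
            n_typical_refs >= 1L, n_atypical_refs >= 1L,
            active_fraction_planted >= 0, active_fraction_planted <= 1,
            active_fraction_decoy >= 0, active_fraction_decoy <= 1,
            binder_score_sd > 0, decoy_score_sd > 0)
  structure(as.list(environment()), class = "generator_config")
}

# evaluate code under a derived seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

# scaffold templates; each has n_sites sprintf slots filled with "" or a
# parenthesized substituent
typical_scaffolds <- function() {
  list(
    list(name = "biphenyl", template = "c1cc%sc%scc1-c1cc%sc%scc1",
         n_sites = 4L),
    list(name = "dibenzodioxin", template = "O1c2cc%sc%scc2Oc2cc%sc%scc12",
         n_sites = 4L),
    list(name = "dibenzofuran", template = "o1c2cc%sc%scc2c2cc%sc%scc12",
         n_sites = 4L),
    list(name = "diphenylether", template = "O(c1cc%sc%scc1)c1cc%sc%scc1",
         n_sites = 4L),
    list(name = "naphthalene", template = "c1cc%sc2cc%sccc2c1",
         n_sites = 2L),
    list(name = "anthracene", template = "c1ccc2cc3cc%sc%scc3cc2c1",
         n_sites = 2L),
    list(name = "phenanthrene", template = "c1ccc2c(c1)ccc1cc%sc%scc21",
         n_sites = 2L),
    list(name = "flavone", template = "O=c1cc(-c2ccc%scc2)oc2cc%sccc12",
         n_sites = 2L),
    list(name = "fluorene", template = "C1c2cc%sc%scc2-c2cc%sc%scc21",
         n_sites = 4L),
    list(name = "dibenzothiophene",
         template = "s1c2cc%sc%scc2c2cc%sc%scc12", n_sites = 4L),
    list(name = "xanthone", template = "O=C1c2cc%sc%scc2Oc2cc%sc%scc21",
         n_sites = 4L),
    list(name = "azobenzene", template = "N(=Nc1cc%sc%scc1)c1cc%sc%scc1",
         n_sites = 4L)
  )
}

atypical_scaffolds <- function() {
  list(
    list(name = "arylpropanamide",
         template = "CC(C)C(=O)Nc1cc%sc([N+](=O)[O-])c(C(F)(F)F)c1",
         n_sites = 1L),
    list(name = "isoxazole_carboxanilide",
         template = "Cc1oncc1C(=O)Nc1cc%sc(C(F)(F)F)cc1", n_sites = 1L),
    list(name = "dihydropyridine",
         template = paste0("COCCOC(=O)C1=C(C)NC(C)=C(C(=O)OC(C)C)",
                           "C1c1cc%scc([N+](=O)[O-])c1"),
         n_sites = 1L),
    list(name = "indole_thiazole",
         template = "COC(=O)c1csc(C(=O)c2c[nH]c3cc%sccc23)n1", n_sites = 1L),
    list(name = "carbazole_aldehyde",
         template = "O=Cc1ccc2c(c1)[nH]c1cc%sccc12", n_sites = 1L)
  )
}

typical_substituents <- function() c("", "", "(Cl)", "(Cl)", "(Br)", "(F)",
                                     "(C)", "(OC)", "(O)",
                                     "([N+](=O)[O-])", "(C#N)", "(CC)")
atypical_substituents <- function() c("", "(C)", "(O)", "(Cl)", "(N)",
                                      "(OC)", "(F)")

# mild single-substituent edits used for planted analogs: halogen swaps,
# methylation/demethylation -- the kind of variation seen between a binder
# and its close industrial analog. Sites carrying heteroatom substituents
# are left untouched so the analog keeps its parent's key substructures.
analog_edit_substituents <- function() c("", "(C)", "(Cl)", "(Br)", "(F)")

fill_template <- function(scaffold, subs) {
  do.call(sprintf, c(list(scaffold$template), as.list(subs)))
}

# draw unique (scaffold, substituent) structures deterministically
draw_structures <- function(n, scaffolds, vocab, seen = character(0)) {
  out_smiles <- character(n)
  out_scaffold <- character(n)
  out_subs <- character(n)
  i <- 1L
  guard <- 0L
  while (i <= n) {
    guard <- guard + 1L
    if (guard > 100L * n + 1000L) stop("scaffold enumeration exhausted")
    sc <- scaffolds[[((i + guard) %% length(scaffolds)) + 1L]]
    subs <- sample(vocab, sc$n_sites, replace = TRUE)
    smi <- fill_template(sc, subs)
    if (smi %in% seen) next
    seen <- c(seen, smi)
    out_smiles[i] <- smi
    out_scaffold[i] <- sc$name
    out_subs[i] <- paste(subs, collapse = "|")
    i <- i + 1L
  }
  data.frame(smiles = out_smiles, scaffold = out_scaffold, subs = out_subs,
             stringsAsFactors = FALSE)
}

#' Generate the reference-binder panel
#'
#' Typical references are drawn from halogenated biphenyl, dibenzodioxin,
#' dibenzofuran, diphenyl-ether, polycyclic-aromatic, and flavone scaffolds
#' with enumerated halogen substitution; atypical references from flexible
#' heteroaromatic scaffolds carrying hydrogen-bond acceptors. All carry a
#' competitive-binding potency at or below 10 micromolar by construction.
#'
#' @param config A [generator_config()].
#' @return Molecule table with extra columns `scaffold`, `subs`,
#'   `is_atypical`.
#' @export
make_reference_binders <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed + 1L, {
    typ <- draw_structures(config$n_typical_refs, typical_scaffolds(),
                           typical_substituents())
    atyp <- draw_structures(config$n_atypical_refs, atypical_scaffolds(),
                            atypical_substituents(), seen = typ$smiles)
    n <- config$n_typical_refs + config$n_atypical_refs
    ids <- c(sprintf("TREF-%04d", seq_len(config$n_typical_refs)),
             sprintf("AREF-%04d", seq_len(config$n_atypical_refs)))
    tab <- molecule_table(ids, c(typ$smiles, atyp$smiles), role = "binder",
                          potency_um = stats::runif(n, 0.01, 10))
    tab$scaffold <- c(typ$scaffold, atyp$scaffold)
    tab$subs <- c(typ$subs, atyp$subs)
    tab$is_atypical <- rep(c(FALSE, TRUE),
                           c(config$n_typical_refs, config$n_atypical_refs))
    tab
  })
}

# single-substituent edit of a parent reference structure; only sites whose
# current substituent is drawn from the edit vocabulary are touched
edit_one_site <- function(parent, scaffolds, vocab, seen) {
  sc <- scaffolds[[match(parent$scaffold, vapply(scaffolds, `[[`, "",
                                                 "name"))]]
  subs <- strsplit(parent$subs, "|", fixed = TRUE)[[1]]
  if (length(subs) == 0L) subs <- rep("", sc$n_sites)
  length(subs) <- sc$n_sites
  subs[is.na(subs)] <- ""
  editable <- which(subs %in% vocab)
  if (length(editable) == 0L) return(NULL)
  sites <- if (length(editable) == 1L) editable else sample(editable)
  for (site in sites) {
    for (alt in sample(setdiff(vocab, subs[site]))) {
      cand <- subs
      cand[site] <- alt
      smi <- fill_template(sc, cand)
      if (!smi %in% seen) {
        return(list(smiles = smi, subs = paste(cand, collapse = "|")))
      }
    }
  }
  NULL
}

# deterministic aliphatic / small-polar decoy structures
decoy_smiles_pool <- function(n) {
  heads <- c("", "O", "N", "OC(=O)", "COC(=O)", "NC(=O)", "OCC(O)",
             "CN(C)")
  tails <- c("", "O", "N", "C(=O)O", "C(=O)OC", "C(C)C", "C(=O)N(C)C",
             "OC(C)C")
  cores <- c("CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CCCCCCC", "CCCCCCCC",
             "CC(C)C", "CC(C)(C)C", "C1CCCCC1", "C1CCCC1", "C1CCOC1",
             "C1CCNCC1", "CC(C)CC(C)", "CCOCC", "CCSCC", "CCOCCOCC",
             "CC(O)CC", "CCNCC", "CC(C)OC(C)")
  grid <- expand.grid(h = heads, co = cores, t = tails,
                      stringsAsFactors = FALSE)
  smi <- unique(paste0(grid$h, grid$co, grid$t))
  if (length(smi) < n) stop("decoy pool too small for requested library")
  smi
}

# monocyclic aromatics with flexible substituents: structurally unlike the
# 2-3 ring reference scaffolds yet close enough in property space to reach
# the parallel screening stage occasionally
near_decoy_pool <- function(n) {
  chains <- c("CCC", "CCCC", "CCCCC", "CC(C)C", "CCO", "CCOC", "CCN(C)C",
              "CCCCCC", "CC(C)CC", "CCOCC")
  aryls <- c("c1ccccc1", "c1ccncc1", "c1ccc(O)cc1", "c1ccc(C)cc1",
             "c1ccc(OC)cc1", "c1ccc(Cl)cc1", "c1ccc(F)cc1",
             "c1ccc(N)cc1")
  smi <- unique(as.vector(outer(chains, aryls, paste0)))
  if (length(smi) < n) stop("near-decoy pool too small")
  smi
}

excluded_element_smiles <- function() {
  c("CC[Pb](CC)(CC)CC", "C[Sn](C)(C)C", "C[As](C)C", "C[Sb](C)C",
    "C[Bi](C)C")
}

#' Generate the candidate library with hidden ground-truth tags
#'
#' Planted analogs are single-substituent edits of reference scaffolds
#' (ground truth `should_hit`); decoys are aliphatic and small polar
#' off-scaffold structures (`should_miss`); a small quota of
#' excluded-element decoys (`excluded`) exercises library curation. The
#' `truth` and `parent_id` columns are generator bookkeeping, invisible to
#' the screen itself.
#'
#' @param config A [generator_config()].
#' @param references Reference table from [make_reference_binders()];
#'   regenerated from `config` when omitted.
#' @return Molecule table with extra columns `truth` and `parent_id`.
#' @export
make_candidate_library <- function(config,
                                   references = make_reference_binders(config)) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed + 2L, {
    seen <- references$smiles
    n_planted <- config$n_planted_analogs
    planted <- vector("list", n_planted)
    parent_rows <- rep(seq_len(nrow(references)), length.out = n_planted)
    for (i in seq_len(n_planted)) {
      edit <- NULL
      for (try in seq_len(nrow(references))) {  # next parent if exhausted
        row <- ((parent_rows[i] - 1L + try - 1L) %% nrow(references)) + 1L
        parent <- references[row, ]
        scaffolds <- if (parent$is_atypical) atypical_scaffolds() else
          typical_scaffolds()
        vocab <- if (parent$is_atypical) {
          unique(atypical_substituents())
        } else {
          analog_edit_substituents()
        }
        edit <- edit_one_site(parent, scaffolds, vocab, seen)
        if (!is.null(edit)) break
      }
      if (is.null(edit)) stop("could not derive a unique analog")
      seen <- c(seen, edit$smiles)
      planted[[i]] <- data.frame(smiles = edit$smiles,
                                 parent_id = parent$id,
                                 stringsAsFactors = FALSE)
    }
    planted <- do.call(rbind, planted)

    n_decoys <- config$n_candidates - n_planted - config$n_near_decoys -
      config$n_excluded_decoys
    pool <- setdiff(decoy_smiles_pool(n_decoys), seen)
    decoys <- sample(pool, n_decoys)
    near <- sample(setdiff(near_decoy_pool(config$n_near_decoys),
                           c(seen, decoys)), config$n_near_decoys)
    excl <- rep_len(excluded_element_smiles(), config$n_excluded_decoys)
    if (config$n_excluded_decoys > length(excluded_element_smiles())) {
      # pad with homologous chains to keep structures unique
      extra <- seq_len(config$n_excluded_decoys -
                         length(excluded_element_smiles()))
      excl[length(excluded_element_smiles()) + extra] <-
        paste0("C", strrep("C", extra), "[Sn](C)(C)C")
    }

    tab <- molecule_table(
      c(sprintf("CAND-A-%04d", seq_len(n_planted)),
        sprintf("CAND-D-%04d", seq_len(n_decoys)),
        sprintf("CAND-N-%04d", seq_len(config$n_near_decoys)),
        sprintf("CAND-X-%02d", seq_len(config$n_excluded_decoys))),
      c(planted$smiles, decoys, near, excl), role = "candidate")
    tab$truth <- rep(c("should_hit", "should_miss", "should_miss",
                       "excluded"),
                     c(n_planted, n_decoys, config$n_near_decoys,
                       config$n_excluded_decoys))
    tab$parent_id <- c(planted$parent_id,
                       rep(NA_character_,
                           n_decoys + config$n_near_decoys +
                             config$n_excluded_decoys))
    tab <- tab[sample(nrow(tab)), , drop = FALSE]
    rownames(tab) <- NULL
    tab
  })
}

#' Generate a synthetic docking-score table
#'
#' Draws a compound-level binding free energy from the class-specific
#' normal distribution (binder-like for references and planted analogs,
#' decoy otherwise), then expands it into ten poses per stereoisomer: the
#' top pose carries the compound value and lower-ranked poses add positive
#' jitter, so the best pose over poses and stereoisomers recovers the
#' compound draw.
#'
#' @param config A [generator_config()].
#' @param compounds Data frame with columns `id` and `truth`
#'   (`should_hit`/`should_miss`/...); references count as binder-like.
#'   Rows tagged `excluded` receive no scores (they never reach docking).
#' @return Per-pose score table with columns `compound_id`,
#'   `stereoisomer_id`, `pose_rank`, `dg_bind_kcal_mol`.
#' @export
make_dock_scores <- function(config, compounds) {
  stopifnot(inherits(config, "generator_config"),
            all(c("id", "truth") %in% names(compounds)))
  compounds <- compounds[compounds$truth != "excluded", , drop = FALSE]
  with_seed(config$seed + 3L, {
    binder_like <- compounds$truth %in% c("reference", "should_hit")
    base <- ifelse(binder_like,
                   stats::rnorm(nrow(compounds), config$binder_score_mean,
                                config$binder_score_sd),
                   stats::rnorm(nrow(compounds), config$decoy_score_mean,
                                config$decoy_score_sd))
    n_stereo <- sample(1:2, nrow(compounds), replace = TRUE)
    out <- vector("list", nrow(compounds))
    for (i in seq_len(nrow(compounds))) {
      rows <- vector("list", n_stereo[i])
      for (s in seq_len(n_stereo[i])) {
        offset <- if (s == 1L) 0 else stats::runif(1, 0.5, 4)
        jitter <- c(0, sort(stats::runif(9, 0.5, 12)))
        rows[[s]] <- data.frame(
          compound_id = compounds$id[i],
          stereoisomer_id = sprintf("S%d", s),
          pose_rank = 1:10,
          dg_bind_kcal_mol = base[i] + offset + jitter,
          stringsAsFactors = FALSE)
      }
      out[[i]] <- do.call(rbind, rows)
    }
    do.call(rbind, out)
  })
}

#' Generate noisy binary activity labels
#'
#' Planted analogs are labeled active with probability
#' `active_fraction_planted`, decoys with `active_fraction_decoy`; the label
#' noise keeps the evaluation metrics non-trivial.
#'
#' @param config A [generator_config()].
#' @param compounds Data frame with `id` and `truth` columns.
#' @return Data frame with columns `id`, `activity`.
#' @export
make_activity_labels <- function(config, compounds) {
  stopifnot(inherits(config, "generator_config"))
  compounds <- compounds[compounds$truth != "excluded", , drop = FALSE]
  with_seed(config$seed + 4L, {
    p <- ifelse(compounds$truth == "should_hit",
                config$active_fraction_planted,
                config$active_fraction_decoy)
    data.frame(id = compounds$id,
               activity = ifelse(stats::runif(nrow(compounds)) < p,
                                 "active", "inactive"),
               stringsAsFactors = FALSE)
  })
}

#' Generate the full synthetic benchmark
#'
#' @param config A [generator_config()].
#' @return List with `references`, `candidates`, `dock_scores`, `labels`.
#' @export
make_screening_benchmark <- function(config) {
  references <- make_reference_binders(config)
  candidates <- make_candidate_library(config, references)
  scored <- rbind(data.frame(id = references$id, truth = "reference",
                             stringsAsFactors = FALSE),
                  candidates[, c("id", "truth")])
  list(references = references,
       candidates = candidates,
       dock_scores = make_dock_scores(config, scored),
       labels = make_activity_labels(config, candidates))
}
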