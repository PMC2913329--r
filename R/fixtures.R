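#' Deterministic synthetic molecule sets
#'
#' Generates labelled sets of small organic molecules with a controlled
#' correlation between the mutagen label and the presence of alert
#' substructures, by substituting alert fragments (nitroaromatic, aromatic
#' amine, epoxide, alkyl halide, nitrosamine, ...) onto benign scaffolds
#' (alkanes, ethers, benzenes). Mutagens carry an alert fragment with
#' probability `alert_mutagen_rate`; non-mutagens with the decoy rate
#' `alert_nonmutagen_rate`. Alert-free mutagens and alert-bearing
#' non-mutagens are therefore present by design, which is what exercises
#' SVM imperfection and the rule-selection audit. Everything is reproducible
#' from the seed.
#'
#' These sets emulate the class balance of a curated Ames corpus (56%
#' mutagens) but not its chemical diversity or property distributions:
#' passing on fixtures demonstrates the machinery, not real-data accuracy.
#'
#' @name fixtures
NULL

# benign scaffold pool: SMILES ending in an attachable atom, with the
# attachment environment they expose (aliphatic sp3 carbon or aromatic ring
# carbon); none of them fires any shipped alert on its own
.fixture_scaffolds <- function() {
  # Building blocks for compositional benign scaffolds: each generated
  # molecule chains 1-3 units (every unit ends in an attachable atom, and
  # chain units start with an aliphatic carbon so concatenation is always
  # valid SMILES and never assembles an alert by accident). The polar units
  # (hydroxyl, ketone, ether, aliphatic amine) deliberately share atom-type
  # signals with the alert fragments, and the combinatorial diversity keeps
  # the descriptor stage from memorising alert contexts — as with real Ames
  # chemistry, so that catchable false negatives exist for the checkpoints.
  # attach: chemistry of the unit's terminal atom; role: usable position.
  data.frame(
    smiles = c("CCC", "CCCC", "CC(C)C", "C1CCCCC1", "c1ccccc1",
               "Cc1ccccc1", "c1ccc2ccccc2c1", "COC", "CC(O)C", "CC(=O)C",
               "CC", "CN(C)C", "CCOC", "CC(C)(C)C", "Cc1ccc(C)cc1"),
    attach = c("aliphatic", "aliphatic", "aliphatic", "aliphatic", "aromatic",
               "aromatic", "aromatic", "aliphatic", "aliphatic", "aliphatic",
               "aliphatic", "aliphatic", "aliphatic", "aliphatic", "aromatic"),
    role = c("both", "both", "both", "first", "first",
             "both", "first", "both", "both", "both",
             "chain", "chain", "chain", "chain", "chain"),
    stringsAsFactors = FALSE)
}

# alert-bearing fragments appended to a scaffold terminus; `attach` says
# which scaffold chemistry the fragment may be grafted onto
.fixture_fragments <- function() {
  data.frame(
    fragment = c("[N+](=O)[O-]",              # aromatic nitro (on arene)
                 "c1ccc([N+](=O)[O-])cc1",    # nitrophenyl (from alkyl)
                 "N",                          # primary aromatic amine
                 "C1OC1",                      # epoxide
                 "CCl",                        # aliphatic chloride
                 "CBr",                        # aliphatic bromide
                 "N(C)N=O",                    # N-nitrosamine
                 "NNC",                        # alkyl hydrazine
                 "C=O",                        # simple aldehyde
                 "C=CC(C)=O",                  # Michael acceptor
                 "N=C=O",                      # isocyanate
                 "N=NN(C)C"),                  # triazene
    attach = c("aromatic", "aliphatic", "aromatic", "both", "both", "both",
               "both", "both", "both", "both", "both", "both"),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic molecule set
#'
#' @param n number of molecules (>= 10).
#' @param frac_mutagen fraction labelled mutagen (default 0.56, the class
#'   balance of curated Ames corpora).
#' @param alert_mutagen_rate probability that a mutagen carries an alert
#'   fragment (default 0.9).
#' @param alert_nonmutagen_rate decoy rate: probability that a non-mutagen
#'   carries one (default 0.1).
#' @param scaffolds,fragments optional custom pools (data frames with the
#'   columns used by the defaults).
#' @param seed integer seed.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n = 1000, frac_mutagen = 0.56,
                         alert_mutagen_rate = 0.9,
                         alert_nonmutagen_rate = 0.1,
                         scaffolds = .fixture_scaffolds(),
                         fragments = .fixture_fragments(),
                         seed = 1) {
  stopifnot(n >= 10, frac_mutagen >= 0, frac_mutagen <= 1,
            alert_mutagen_rate >= 0, alert_mutagen_rate <= 1,
            alert_nonmutagen_rate >= 0, alert_nonmutagen_rate <= 1)
  if (!nrow(scaffolds)) stop("empty scaffold pool", call. = FALSE)
  structure(list(n = as.integer(n), frac_mutagen = frac_mutagen,
                 alert_mutagen_rate = alert_mutagen_rate,
                 alert_nonmutagen_rate = alert_nonmutagen_rate,
                 scaffolds = scaffolds, fragments = fragments,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic labelled molecule set
#'
#' @param spec a [fixture_spec()].
#' @return a standardized `molecule_set` with `ames_label` filled in and an
#'   attribute `fixture_design` (data frame: scaffold, fragment, has_alert).
#' @examples
#' ms <- generate_molecules(fixture_spec(n = 20, seed = 7))
#' table(ms$records$ames_label)
#' @export
generate_molecules <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  sc <- spec$scaffolds; fr <- spec$fragments
  first_pool <- which(sc$role %in% c("first", "both"))
  chain_pool <- which(sc$role %in% c("chain", "both"))
  design <- .with_seed(spec$seed, {
    lab <- ifelse(stats::runif(spec$n) < spec$frac_mutagen,
                  "mutagen", "nonmutagen")
    rate <- ifelse(lab == "mutagen", spec$alert_mutagen_rate,
                   spec$alert_nonmutagen_rate)
    has_alert <- stats::runif(spec$n) < rate
    scaffold <- character(spec$n)
    attach <- character(spec$n)
    frag <- rep(NA_character_, spec$n)
    for (i in seq_len(spec$n)) {
      units <- sample(first_pool, 1L)
      for (k in seq_len(sample(0:2, 1L))) {
        # a unit with an aromatic terminus can only end the chain
        if (sc$attach[units[length(units)]] == "aromatic") break
        units <- c(units, sample(chain_pool, 1L))
      }
      scaffold[i] <- paste(sc$smiles[units], collapse = "")
      attach[i] <- sc$attach[units[length(units)]]
      if (has_alert[i]) {
        compat <- fr$attach == "both" | fr$attach == attach[i]
        frag[i] <- fr$fragment[sample(which(compat), 1L)]
      }
    }
    data.frame(scaffold = scaffold, fragment = frag,
               has_alert = has_alert, ames_label = lab,
               stringsAsFactors = FALSE)
  })
  smi <- ifelse(design$has_alert,
                paste0(design$scaffold, design$fragment),
                design$scaffold)
  ms <- molecules_from_smiles(smi,
                              mol_id = sprintf("FIX%05d", seq_len(spec$n)),
                              ames_label = design$ames_label,
                              standardize = TRUE)
  attr(ms, "fixture_design") <- design
  ms
}
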