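#' Simulation configuration for clade-structured haplotype data
#'
#' Describes the generative model the analysis stages assume: several
#' divergent clades of closely related AT-rich haplotypes. A single root
#' sequence is drawn i.i.d. per site from `base_freqs`; each clade ancestor
#' is separated from the root by a Poisson(`between_clade_divergence`)
#' number of substitutions along a star; each tip adds a
#' Poisson(`within_clade_lambda`) number of substitutions at distinct,
#' uniformly chosen sites (target base drawn from `base_freqs` excluding
#' the current state). Tips in neustonic clades are then passed through
#' [suppress_tt_words()] with `tt_suppression`, creating a habitat-linked
#' deficit of photolesion-promoting TTA/TTT motifs.
#'
#' Defaults reflect the study system the generator emulates: a ~1100 nt
#' AT-rich mitochondrial rRNA fragment, clade-level mean pairwise
#' differences around 2 x `within_clade_lambda` = 10, and strongly
#' divergent clade ancestors.
#'
#' @param n_clades number of clades (>= 1).
#' @param seqs_per_clade tips per clade (>= 2).
#' @param seq_length sites per sequence (>= 10; default 1100).
#' @param base_freqs named probability vector over `A`,`C`,`G`,`T` summing
#'   to 1 (default AT-rich: A=0.35, C=0.15, G=0.20, T=0.30).
#' @param within_clade_lambda Poisson mean of tip-to-ancestor substitutions.
#' @param between_clade_divergence Poisson mean of root-to-clade-ancestor
#'   substitutions.
#' @param habitat_assignment named character vector clade label -> habitat
#'   (`neustonic`/`planktonic`); default: first half of the clades
#'   neustonic, the rest planktonic.
#' @param tt_suppression factor in `[0, 1]` passed to
#'   [suppress_tt_words()]; 1 (default) means no suppression.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_clades = 4L, seqs_per_clade = 25L,
                       seq_length = 1100L,
                       base_freqs = c(A = 0.35, C = 0.15, G = 0.20, T = 0.30),
                       within_clade_lambda = 5,
                       between_clade_divergence = 60,
                       habitat_assignment = NULL,
                       tt_suppression = 1,
                       seed = 1L) {
  if (seq_length < 10L)
    ns_stop("neustonet_config", "seq_length must be >= 10")
  if (n_clades < 1L || seqs_per_clade < 2L)
    ns_stop("neustonet_config", "need n_clades >= 1 and seqs_per_clade >= 2")
  if (!setequal(names(base_freqs), c("A", "C", "G", "T")) ||
      any(base_freqs < 0) || abs(sum(base_freqs) - 1) > 1e-9)
    ns_stop("neustonet_config",
            "base_freqs must be a named A/C/G/T probability vector summing to 1")
  if (tt_suppression < 0 || tt_suppression > 1)
    ns_stop("neustonet_config", "tt_suppression must be in [0, 1]")
  clades <- LETTERS[seq_len(n_clades)]
  if (is.null(habitat_assignment)) {
    habitat_assignment <- rep(c("neustonic", "planktonic"),
                              c(ceiling(n_clades / 2), floor(n_clades / 2)))
    names(habitat_assignment) <- clades
  }
  if (!setequal(names(habitat_assignment), clades) ||
      !all(habitat_assignment %in% c("neustonic", "planktonic")))
    ns_stop("neustonet_config", "habitat_assignment must map every clade to neustonic|planktonic")
  structure(list(n_clades = as.integer(n_clades),
                 seqs_per_clade = as.integer(seqs_per_clade),
                 seq_length = as.integer(seq_length),
                 base_freqs = base_freqs[c("A", "C", "G", "T")],
                 within_clade_lambda = within_clade_lambda,
                 between_clade_divergence = between_clade_divergence,
                 habitat_assignment = habitat_assignment[clades],
                 tt_suppression = tt_suppression,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Poisson draw truncated to <= L, resampling (with a warning) when exceeded
rpois_capped <- function(lambda, L) {
  k <- stats::rpois(1L, lambda)
  while (k > L) {
    ns_warn("neustonet_resample",
            "mutation count %d exceeds sequence length %d; resampled", k, L)
    k <- stats::rpois(1L, lambda)
  }
  k
}

# mutate `k` distinct uniformly chosen sites of character vector `x`;
# target base drawn from base_freqs excluding the current state
mutate_sites <- function(x, k, base_freqs) {
  if (k == 0L) return(list(x = x, sites = integer(0), to = character(0)))
  sites <- sample.int(length(x), k)
  to <- vapply(sites, function(s) {
    pool <- setdiff(c("A", "C", "G", "T"), x[s])
    p <- base_freqs[pool]
    sample(pool, 1L, prob = p / sum(p))
  }, character(1))
  x[sites] <- to
  list(x = x, sites = sites, to = to)
}

#' Simulate a clade-structured haplotype dataset
#'
#' Runs the generative model described in [sim_config()] and returns the
#' sequences (as an alignment: the model has no indels), the clade/habitat
#' group map, and a ground-truth record sufficient to reproduce every
#' realized mutation — the oracle used by parameter-recovery tests.
#'
#' @param config a [sim_config()].
#' @return a list with elements `sequences` ([sequence_set()]), `groups`
#'   (`group_map`), and `truth` (per-clade ancestors and per-tip mutation
#'   lists, expected pairwise difference `2 * within_clade_lambda`, and
#'   per-habitat promoter-motif densities before and after suppression).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$seq_length
  bases <- c("A", "C", "G", "T")
  freqs <- config$base_freqs
  root <- sample(bases, L, replace = TRUE, prob = freqs)
  clades <- names(config$habitat_assignment)
  seqs <- character(0); ids <- character(0)
  map <- list(); truth_clades <- list()
  pre_density <- list(neustonic = numeric(0), planktonic = numeric(0))
  post_density <- list(neustonic = numeric(0), planktonic = numeric(0))
  pre_inhib <- list(neustonic = numeric(0), planktonic = numeric(0))
  post_inhib <- list(neustonic = numeric(0), planktonic = numeric(0))
  for (cl in clades) {
    anc_mut <- mutate_sites(root, rpois_capped(config$between_clade_divergence, L),
                            freqs)
    anc <- anc_mut$x
    habitat <- config$habitat_assignment[[cl]]
    tips <- list()
    for (i in seq_len(config$seqs_per_clade)) {
      id <- sprintf("%s_%02d", cl, i)
      k <- rpois_capped(config$within_clade_lambda, L)
      tip <- mutate_sites(anc, k, freqs)
      s <- paste(tip$x, collapse = "")
      pre <- count_overlapping(s, "TTA") + count_overlapping(s, "TTT")
      pre_i <- count_overlapping(s, "TTC") + count_overlapping(s, "TTG")
      if (habitat == "neustonic" && config$tt_suppression < 1)
        s <- suppress_tt_words(s, config$tt_suppression, freqs)
      post <- count_overlapping(s, "TTA") + count_overlapping(s, "TTT")
      post_i <- count_overlapping(s, "TTC") + count_overlapping(s, "TTG")
      pre_density[[habitat]] <- c(pre_density[[habitat]], pre / L)
      post_density[[habitat]] <- c(post_density[[habitat]], post / L)
      pre_inhib[[habitat]] <- c(pre_inhib[[habitat]], pre_i / L)
      post_inhib[[habitat]] <- c(post_inhib[[habitat]], post_i / L)
      seqs <- c(seqs, s); ids <- c(ids, id)
      map[[length(map) + 1L]] <- data.frame(id = id, clade = cl,
                                            habitat = habitat,
                                            stringsAsFactors = FALSE)
      tips[[id]] <- list(n_mutations = k, sites = tip$sites, to = tip$to)
    }
    truth_clades[[cl]] <- list(ancestor = paste(anc, collapse = ""),
                               tips = tips,
                               expected_pairwise_diff = 2 * config$within_clade_lambda)
  }
  names(seqs) <- ids
  list(sequences = sequence_set(seqs, is_alignment = TRUE),
       groups = group_map(do.call(rbind, map)),
       truth = list(clades = truth_clades,
                    promoter_density_pre = pre_density,
                    promoter_density_post = post_density,
                    inhibitor_density_pre = pre_inhib,
                    inhibitor_density_post = post_inhib,
                    seed = config$seed,
                    config = unclass(config)))
}

#' Suppress photolesion-promoting TT words in a sequence
#'
#' Scans the plus strand of the input for overlapping occurrences of the
#' promoter motifs `TTA` and `TTT` and destroys each occurrence
#' independently with probability `1 - factor` by replacing its third base
#' with a draw from `{C, G}` weighted by `base_freqs`. Decisions are made
#' against the *original* occurrence list in a single pass; because the
#' substituted base is never a `T`, destruction cannot create new promoter
#' words, so `factor = 0` provably leaves zero TTA/TTT occurrences. The
#' complementary deficit on the minus strand emerges automatically from the
#' complementary words. Output length is unchanged. Uses the current RNG
#' stream.
#'
#' @param seq a residue string.
#' @param factor survival probability in `[0, 1]`; 1 is the identity.
#' @param base_freqs named base frequencies (only `C` and `G` are used).
#' @return the (possibly) modified residue string.
#' @export
suppress_tt_words <- function(seq, factor,
                              base_freqs = c(A = 0.35, C = 0.15, G = 0.20, T = 0.30)) {
  if (factor < 0 || factor > 1)
    ns_stop("neustonet_config", "factor must be in [0, 1]")
  if (factor == 1) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n < 3L) return(seq)
  hits <- which(ch[1:(n - 2L)] == "T" & ch[2:(n - 1L)] == "T" &
                ch[3:n] %in% c("A", "T"))
  if (!length(hits)) return(seq)
  destroy <- stats::runif(length(hits)) >= factor
  if (any(destroy)) {
    p <- base_freqs[c("C", "G")]
    repl <- sample(c("C", "G"), sum(destroy), replace = TRUE, prob = p / sum(p))
    ch[hits[destroy] + 2L] <- repl
  }
  paste(ch, collapse = "")
}
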