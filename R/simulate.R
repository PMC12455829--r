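#' Configuration for a simulated IP-QMS experiment
#'
#' The generator states a simple capture model for affinity purification. Each
#' protein has a log-normal base abundance in the lysate. An IgG control
#' captures `igg_background_fraction` of every protein's base abundance
#' (non-specific binding). A bait IP captures complexes: the bait and all
#' complex (catalog) members are enriched `bait_enrichment`-fold over IgG
#' (efficient pulldowns show > 15-fold target enrichment; the default 20
#' satisfies that), true interactors and a fusion bait seen from another IP
#' sit at `interactor_enrichment` (> 4-fold, the typical co-IP signal), and
#' background proteins at 1 (indistinguishable from IgG). Replicate noise is
#' multiplicative log-normal with coefficient of variation `replicate_cv`,
#' mean-corrected to 1 so that ratios of group means are unbiased. Values
#' below `detection_floor` are censored to missing (missing-not-at-random by
#' construction).
#'
#' With these defaults the model-implied bait-normalized stoichiometry of a
#' fusion bait (its own IP versus a BRG1 IP) is
#' `bait_enrichment / interactor_enrichment = 5`.
#'
#' @param n_proteins Total proteins simulated (catalog genes and baits are
#'   embedded in this namespace).
#' @param baits List of length-2 character vectors `c(bait_gene, context)`.
#' @param n_replicates Replicates per IP (and per IgG group); >= 2.
#' @param base_abundance Named numeric `c(mu, sigma)` of the natural-log
#'   normal base abundance.
#' @param igg_background_fraction Fraction of base abundance captured
#'   non-specifically, in `[0, 1]`.
#' @param bait_enrichment Enrichment of the bait and complex members over IgG
#'   in a bait IP.
#' @param interactor_enrichment Enrichment of true interactors over IgG.
#' @param fraction_interactor Fraction of non-catalog, non-bait proteins that
#'   are true interactors.
#' @param fraction_igg_only Fraction of proteins present only in IgG controls
#'   (absent from every bait IP).
#' @param planted_enrichment List of `list(class=, ip="BAIT:CTX", factor=)`
#'   entries; each multiplies the named truth class's capture level in one IP.
#' @param ip_yield Named numeric, per-IP ("BAIT:CTX") yield multipliers
#'   applied to all specific capture (default 1); values well below 1 emulate
#'   a failed pulldown.
#' @param detection_floor Abundance below which values are censored to
#'   missing.
#' @param replicate_cv Coefficient of variation of replicate noise.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List of class `ip_sim_config`.
#' @export
ip_sim_config <- function(n_proteins = 2000,
                          baits = list(c("BRG1", "MLS"), c("BRG1", "EWS"),
                                       c("DDIT3", "MLS")),
                          n_replicates = 3L,
                          base_abundance = c(mu = log(100), sigma = 1),
                          igg_background_fraction = 0.1,
                          bait_enrichment = 20,
                          interactor_enrichment = 4,
                          fraction_interactor = 0.5,
                          fraction_igg_only = 0.01,
                          planted_enrichment = list(),
                          ip_yield = NULL,
                          detection_floor = 1,
                          replicate_cv = 0.2,
                          seed = 1L) {
  if (n_replicates < 2L) abort_ipqms("n_replicates must be >= 2")
  if (igg_background_fraction < 0 || igg_background_fraction > 1) {
    abort_ipqms("igg_background_fraction must be in [0, 1]")
  }
  stopifnot_scalar_number(bait_enrichment, "bait_enrichment", positive = TRUE)
  stopifnot_scalar_number(interactor_enrichment, "interactor_enrichment",
                          positive = TRUE)
  for (pe in planted_enrichment) {
    if (!all(c("class", "ip", "factor") %in% names(pe))) {
      abort_ipqms("planted_enrichment entries need class, ip, factor")
    }
    if (pe$factor <= 0) abort_ipqms("planted factors must be > 0")
  }
  structure(list(n_proteins = n_proteins, baits = baits,
                 n_replicates = as.integer(n_replicates),
                 base_abundance = base_abundance,
                 igg_background_fraction = igg_background_fraction,
                 bait_enrichment = bait_enrichment,
                 interactor_enrichment = interactor_enrichment,
                 fraction_interactor = fraction_interactor,
                 fraction_igg_only = fraction_igg_only,
                 planted_enrichment = planted_enrichment,
                 ip_yield = ip_yield,
                 detection_floor = detection_floor,
                 replicate_cv = replicate_cv,
                 seed = seed),
            class = "ip_sim_config")
}

#' Simulate an IP-QMS experiment with known ground truth
#'
#' @param config An [ip_sim_config()].
#' @param catalog A `swisnf_catalog`; its genes are embedded in the protein
#'   namespace as complex members.
#' @return List with `matrix` (proteins x samples, provenance `"raw"`,
#'   missing below the detection floor), `design` (`ip_design`), and `truth`:
#'   a data frame aligned 1:1 with the matrix rows carrying `protein`,
#'   `class` (bait / subunit_class / interactor / igg_only / background) and
#'   one `effect_<BAIT.CTX>` column per IP with the true enrichment over IgG.
#'   Use [true_fold_change()] to obtain implied bait-normalized fold changes.
#' @export
simulate_ip_experiment <- function(config, catalog = load_catalog()) {
  bait_genes <- unique(vapply(config$baits, `[`, "", 1L))
  contexts <- unique(vapply(config$baits, `[`, "", 2L))
  cat_genes <- setdiff(catalog$gene_symbol, bait_genes)
  n_named <- length(bait_genes) + length(cat_genes)
  if (config$n_proteins < n_named) {
    abort_ipqms("n_proteins smaller than catalog + bait namespace")
  }
  n_anon <- config$n_proteins - n_named
  anon <- sprintf("PROT%05d", seq_len(n_anon))
  proteins <- c(bait_genes, cat_genes, anon)

  ips <- vapply(config$baits, function(b) ip_key(b[1], b[2]), "")
  yield <- stats::setNames(rep(1, length(ips)), ips)
  if (!is.null(config$ip_yield)) {
    yield[names(config$ip_yield)] <- config$ip_yield
  }

  with_seed(config$seed, {
    # protein truth classes
    class <- rep("background", length(proteins))
    names(class) <- proteins
    class[bait_genes] <- "bait"
    class[cat_genes] <- catalog$subunit_class[match(cat_genes,
                                                    catalog$gene_symbol)]
    n_int <- round(config$fraction_interactor * n_anon)
    n_igg <- round(config$fraction_igg_only * n_anon)
    roles <- sample(anon, n_int + n_igg)
    class[roles[seq_len(n_int)]] <- "interactor"
    if (n_igg > 0) class[roles[n_int + seq_len(n_igg)]] <- "igg_only"

    # per-IP enrichment over IgG (truth effects)
    effects <- matrix(1, nrow = length(proteins), ncol = length(ips),
                      dimnames = list(proteins, ips))
    for (k in seq_along(ips)) {
      b <- config$baits[[k]]
      e <- rep(1, length(proteins))
      e[class %in% c(subunit_classes)] <- config$bait_enrichment
      e[class == "interactor"] <- config$interactor_enrichment
      # bait genes outside the catalog (e.g. a fusion oncoprotein) behave as
      # interactors when another bait is pulled down; catalog baits (BRG1)
      # ride on the captured complexes as members in every SWI/SNF-directed IP
      e[proteins %in% setdiff(bait_genes, catalog$gene_symbol)] <-
        config$interactor_enrichment
      e[proteins %in% intersect(bait_genes, catalog$gene_symbol)] <-
        config$bait_enrichment
      e[proteins == b[1]] <- config$bait_enrichment
      e[class == "igg_only"] <- 0
      effects[, k] <- e * yield[k]
    }
    for (pe in config$planted_enrichment) {
      sel <- class == pe$class
      if (!any(sel)) abort_ipqms(sprintf("planted class '%s' has no proteins",
                                         pe$class))
      if (!pe$ip %in% ips) abort_ipqms(sprintf("planted ip '%s' not simulated",
                                               pe$ip))
      effects[sel, pe$ip] <- effects[sel, pe$ip] * pe$factor
    }

    base <- stats::rlnorm(length(proteins),
                          meanlog = config$base_abundance[["mu"]],
                          sdlog = config$base_abundance[["sigma"]])

    # design: IgG per context first, then bait IPs
    des <- list()
    for (ctx in contexts) {
      des[[length(des) + 1L]] <- data.frame(
        sample_id = sprintf("IgG_%s_r%d", ctx, seq_len(config$n_replicates)),
        ip_target = "IgG", cell_context = ctx,
        replicate = seq_len(config$n_replicates), is_control = TRUE)
    }
    for (b in config$baits) {
      des[[length(des) + 1L]] <- data.frame(
        sample_id = sprintf("%s_%s_r%d", b[1], b[2],
                            seq_len(config$n_replicates)),
        ip_target = b[1], cell_context = b[2],
        replicate = seq_len(config$n_replicates), is_control = FALSE)
    }
    des <- do.call(rbind, des)
    design <- ip_design(des$sample_id, des$ip_target, des$cell_context,
                        des$replicate, des$is_control)

    # expected value per (protein, sample); IgG effect is 1 by definition
    expec <- matrix(NA_real_, nrow = length(proteins), ncol = nrow(design),
                    dimnames = list(proteins, design$sample_id))
    for (j in seq_len(nrow(design))) {
      e <- if (design$is_control[j]) rep(1, length(proteins))
           else effects[, ip_key(design$ip_target[j], design$cell_context[j])]
      expec[, j] <- base * config$igg_background_fraction * e
    }
    s <- sqrt(log(1 + config$replicate_cv^2))
    noise <- matrix(stats::rlnorm(length(expec), meanlog = -s^2 / 2, sdlog = s),
                    nrow = nrow(expec))
    m <- expec * noise
    m[m < config$detection_floor | expec == 0] <- NA_real_
    attr(m, "provenance") <- "raw"

    truth <- data.frame(protein = proteins, class = unname(class),
                        stringsAsFactors = FALSE)
    for (k in seq_along(ips)) {
      truth[[paste0("effect_", gsub(":", ".", ips[k]))]] <- effects[, k]
    }
    list(matrix = m, design = design, truth = truth)
  })
}

#' Model-implied bait-normalized fold change
#'
#' Computes, from a simulation truth table, the exact fold change each protein
#' would show in a comparison of two IPs after bait normalization:
#' `(E_p(a) / E_bait(a)) / (E_p(b) / E_bait(b))` where `E` is the true
#' enrichment over IgG (base abundances cancel).
#'
#' @param truth Truth table from [simulate_ip_experiment()].
#' @param ip_a,ip_b IP keys, e.g. `"DDIT3:MLS"`.
#' @param bait Normalization bait gene symbol.
#' @return Named numeric vector of true fold changes (NA for proteins absent
#'   from an IP).
#' @export
true_fold_change <- function(truth, ip_a, ip_b, bait = "BRG1") {
  ca <- paste0("effect_", gsub(":", ".", ip_a))
  cb <- paste0("effect_", gsub(":", ".", ip_b))
  if (!all(c(ca, cb) %in% names(truth))) {
    abort_ipqms("truth table lacks the requested IP effect columns")
  }
  i <- match(bait, truth$protein)
  if (is.na(i)) abort_ipqms("bait not present in truth table")
  fc <- (truth[[ca]] / truth[[ca]][i]) / (truth[[cb]] / truth[[cb]][i])
  fc[truth[[ca]] == 0 | truth[[cb]] == 0] <- NA_real_
  stats::setNames(fc, truth$protein)
}

#' Simulate a single-cell detection matrix
#'
#' Each gene is detected per cell with its stated probability; positive cells
#' receive a count of `1 + Poisson(count_lambda)`. One optional planted
#' pairwise dependency sets the odds ratio of the joint detection of two genes
#' while preserving their marginals (Plackett-type 2x2 construction).
#'
#' @param n_cells Number of cells.
#' @param gene_probs Named numeric vector of per-gene detection probabilities
#'   in `[0, 1]`.
#' @param dependency Optional `list(gene_i=, gene_j=, odds_multiplier=)`;
#'   `odds_multiplier > 0` is the joint-detection odds ratio (1 =
#'   independence).
#' @param seed Integer seed.
#' @param count_lambda Poisson mean of counts above the detection threshold.
#' @return Integer matrix (genes x cells) of counts.
#' @export
simulate_sc_counts <- function(n_cells, gene_probs, dependency = NULL,
                               seed = 1L, count_lambda = 1) {
  if (is.null(names(gene_probs)) || any(names(gene_probs) == "")) {
    abort_ipqms("gene_probs must be a named vector")
  }
  if (any(gene_probs < 0 | gene_probs > 1)) {
    abort_ipqms("detection probabilities must be in [0, 1]")
  }
  with_seed(seed, {
    genes <- names(gene_probs)
    pos <- matrix(FALSE, nrow = length(genes), ncol = n_cells,
                  dimnames = list(genes, sprintf("cell%05d", seq_len(n_cells))))
    dep_genes <- character()
    if (!is.null(dependency)) {
      gi <- dependency$gene_i; gj <- dependency$gene_j
      theta <- dependency$odds_multiplier
      if (is.null(theta) || theta <= 0) {
        abort_ipqms("odds_multiplier must be > 0")
      }
      if (!all(c(gi, gj) %in% genes)) {
        abort_ipqms("dependency genes must appear in gene_probs")
      }
      p11 <- joint_prob_from_odds(gene_probs[[gi]], gene_probs[[gj]], theta)
      pi <- gene_probs[[gi]]; pj <- gene_probs[[gj]]
      cell_cat <- sample.int(4L, n_cells, replace = TRUE,
                             prob = c(p11, pi - p11, pj - p11,
                                      1 - pi - pj + p11))
      pos[gi, ] <- cell_cat %in% c(1L, 2L)
      pos[gj, ] <- cell_cat %in% c(1L, 3L)
      dep_genes <- c(gi, gj)
    }
    for (g in setdiff(genes, dep_genes)) {
      pos[g, ] <- stats::runif(n_cells) < gene_probs[[g]]
    }
    counts <- matrix(0L, nrow = nrow(pos), ncol = ncol(pos),
                     dimnames = dimnames(pos))
    npos <- sum(pos)
    counts[pos] <- 1L + stats::rpois(npos, count_lambda)
    counts
  })
}

# p11 of a 2x2 joint distribution with marginals (pi, pj) and odds ratio
# theta: root of (1-theta) x^2 + (1 + (theta-1)(pi+pj)) x - theta pi pj = 0
# lying inside the Frechet bounds.
joint_prob_from_odds <- function(pi, pj, theta) {
  if (theta == 1) return(pi * pj)
  b <- 1 + (theta - 1) * (pi + pj)
  disc <- b^2 - 4 * theta * (theta - 1) * pi * pj
  p11 <- (b - sqrt(disc)) / (2 * (theta - 1))
  lo <- max(0, pi + pj - 1); hi <- min(pi, pj)
  min(max(p11, lo), hi)
}

#' Simulate transcription-factor evidence with known labels
#'
#' Generates per-TF direction calls from three evidence streams (chromatin
#' motif enrichment, IP enrichment, RNA regulation) consistent with a sampled
#' truth label, then corrupts each stream independently with probability
#' `noise_rate` (replacing it by a uniformly chosen different value of its
#' enum).
#'
#' @param n_tfs Number of transcription factors.
#' @param label_mix Named numeric proportions over
#'   `c("a_specific", "b_specific", "shared", "unassigned")`; must sum to 1.
#' @param noise_rate Per-stream corruption probability.
#' @param seed Integer seed.
#' @return List with `evidence` (data frame tf/motif_call/ip_call/rna_call)
#'   and `truth` (data frame tf/label).
#' @export
simulate_tf_evidence <- function(n_tfs,
                                 label_mix = c(a_specific = 0.25,
                                               b_specific = 0.25,
                                               shared = 0.2,
                                               unassigned = 0.3),
                                 noise_rate = 0, seed = 1L) {
  if (abs(sum(label_mix) - 1) > 1e-8) {
    abort_ipqms("label_mix proportions must sum to 1")
  }
  bad <- setdiff(names(label_mix),
                 c("a_specific", "b_specific", "shared", "unassigned"))
  if (length(bad)) {
    abort_ipqms(paste0("unknown label(s) in label_mix: ",
                       paste(bad, collapse = ", ")))
  }
  with_seed(seed, {
    tf <- sprintf("TF%04d", seq_len(n_tfs))
    labels <- sample(names(label_mix), n_tfs, replace = TRUE,
                     prob = unname(label_mix))
    specific_patterns <- function(d) {
      list(c(d, d, "none"), c(d, "none", d), c("none", d, d), c(d, d, d))
    }
    unassigned_patterns <- list(
      c("none", "none", "none"),
      c("cond_a", "none", "none"), c("cond_b", "none", "none"),
      c("none", "cond_a", "none"), c("none", "cond_b", "none"),
      c("none", "none", "cond_a"), c("none", "none", "cond_b"))
    ev <- t(vapply(labels, function(lab) {
      switch(lab,
        a_specific = {
          ps <- specific_patterns("cond_a"); ps[[sample.int(4L, 1L)]]
        },
        b_specific = {
          ps <- specific_patterns("cond_b"); ps[[sample.int(4L, 1L)]]
        },
        shared = c("shared_open", "none", "none"),
        unassigned = unassigned_patterns[[sample.int(7L, 1L)]])
    }, character(3)))
    motif_vals <- c("cond_a", "cond_b", "shared_open", "none")
    dir_vals <- c("cond_a", "cond_b", "none")
    corrupt <- function(x, vals) {
      hit <- stats::runif(length(x)) < noise_rate
      for (i in which(hit)) x[i] <- sample(setdiff(vals, x[i]), 1L)
      x
    }
    evidence <- data.frame(tf = tf,
                           motif_call = corrupt(ev[, 1], motif_vals),
                           ip_call = corrupt(ev[, 2], dir_vals),
                           rna_call = corrupt(ev[, 3], dir_vals),
                           row.names = NULL, stringsAsFactors = FALSE)
    list(evidence = evidence,
         truth = data.frame(tf = tf, label = labels,
                            stringsAsFactors = FALSE))
  })
}
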