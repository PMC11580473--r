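# Seeded simulators providing ground truth for every pipeline stage:
# genomes with planted motifs, annotations with known upstream placements,
# Yule trees, and traits drawn from the model covariances.

.ZDNA_UNITS <- c("TG", "CA", "GT", "AC", "GC", "CG")
# non-Z-forming STR units (every unit boundary breaks purine/pyrimidine
# alternation; <= 5 bp so alternating stretches stay < 10 nt)
.STR_UNITS <- c("GAT", "AAG", "CCT", "AGG", "CTT", "AATC", "AAGG",
                "TTAGG", "AATAG", "AAT", "TTC")

.rand_dna <- function(n, gc = 0.42) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.base_class <- function(b) ifelse(b %in% c("A", "G"), "R", "Y")

# Would placing base b next to edge base e form a Z-valid step?
.z_step_valid <- function(b, e, allow_at = FALSE) {
  ok <- .base_class(b) != .base_class(e)
  if (!allow_at) ok <- ok & !(sort(c(b, e))[1L] == "A" & sort(c(b, e))[2L] == "T")
  ok
}

#' Simulation configuration for synthetic genomes
#'
#' @param seed Mandatory RNG seed.
#' @param contig_lengths Named integer vector of contig lengths (bp).
#' @param gc GC content of the background sequence.
#' @param n_zdna,n_str Number of planted Z-DNA / STR tracts per contig.
#' @param mode `"planted_only"` (background scrubbed free of valid motifs,
#'   truth known exactly; contigs capped at 5 Mb) or `"oracle"` (background
#'   left as drawn; truth obtained by scanning the emitted sequence).
#' @param params Scanner parameters the truth refers to.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, contig_lengths = c(chr1 = 100000L), gc = 0.42,
                       n_zdna = 10L, n_str = 10L,
                       mode = c("planted_only", "oracle"),
                       params = scan_params()) {
  mode <- match.arg(mode)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      is.na(seed))
    stop("a single integer seed is mandatory")
  if (is.null(names(contig_lengths)) || any(!nzchar(names(contig_lengths))))
    stop("contig_lengths must be named")
  if (any(contig_lengths < 100))
    stop("contigs must be at least 100 bp")
  if (mode == "planted_only" && any(contig_lengths > 5e6))
    stop("planted_only mode caps contigs at 5 Mb; use mode = 'oracle'")
  if (!is.numeric(gc) || gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  structure(list(seed = as.integer(seed),
                 contig_lengths = contig_lengths, gc = gc,
                 n_zdna = as.integer(n_zdna), n_str = as.integer(n_str),
                 mode = mode, params = params),
            class = "sim_config")
}

# Draw one plant: payload string plus its analytic truth hits (coordinates
# relative to payload start = 1).
.draw_plant <- function(motif_class, params) {
  if (motif_class == "ZDNA") {
    unit <- sample(.ZDNA_UNITS, 1L)
    min_copies <- max(5L, ceiling(params$zdna_min_len / 2),
                      params$str_min_copies,
                      ceiling(params$str_min_len / 2))
    copies <- sample(min_copies:(min_copies + 7L), 1L)
    payload <- strrep(unit, copies)
    len <- nchar(payload)
    truth <- data.frame(
      start = 1L, stop = len, length = len, motif_class = "ZDNA",
      unit = "", copies = NA_integer_, sequence = payload,
      stringsAsFactors = FALSE
    )
    # an alternating dinucleotide tandem is also a perfect STR
    if (nchar(unit) >= params$str_unit_min &&
        nchar(unit) <= params$str_unit_max &&
        copies >= params$str_min_copies && len >= params$str_min_len)
      truth <- rbind(truth, data.frame(
        start = 1L, stop = len, length = len, motif_class = "STR",
        unit = unit, copies = copies, sequence = payload,
        stringsAsFactors = FALSE
      ))
  } else {
    units <- .STR_UNITS[nchar(.STR_UNITS) >= params$str_unit_min &
                        nchar(.STR_UNITS) <= params$str_unit_max]
    if (length(units) == 0L)
      stop("no STR payload unit available for the active unit-size range")
    unit <- sample(units, 1L)
    u <- nchar(unit)
    copies <- max(params$str_min_copies, ceiling(params$str_min_len / u)) +
      sample(0:4, 1L)
    partial <- sample(0:(u - 1L), 1L)
    payload <- paste0(strrep(unit, copies), substr(unit, 1L, partial))
    len <- nchar(payload)
    truth <- data.frame(
      start = 1L, stop = len, length = len, motif_class = "STR",
      unit = unit, copies = as.integer(copies), sequence = payload,
      stringsAsFactors = FALSE
    )
  }
  list(payload = payload, truth = truth, unit_len = nchar(unit))
}

# Replace detected motifs in a background sequence until the scan is clean.
.scrub_background <- function(seq, seq_id, params, max_iter = 100L) {
  bases <- c("A", "C", "G", "T")
  for (iter in seq_len(max_iter)) {
    hits <- rbind(scan_zdna(seq, seq_id, params),
                  scan_str(seq, seq_id, params))
    if (nrow(hits) == 0L) return(seq)
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    for (h in seq_len(nrow(hits))) {
      j <- (hits$start[[h]] + hits$stop[[h]]) %/% 2L
      avoid <- ch[[j]]
      for (u in params$str_unit_min:params$str_unit_max) {
        if (j - u >= 1L) avoid <- c(avoid, ch[[j - u]])
        if (j + u <= length(ch)) avoid <- c(avoid, ch[[j + u]])
      }
      cand <- setdiff(bases, avoid)
      if (length(cand) == 0L) cand <- setdiff(bases, ch[[j]])
      ch[[j]] <- sample(cand, 1L)
    }
    seq <- paste(ch, collapse = "")
  }
  stop("background scrub did not converge after ", max_iter, " iterations")
}

# After planting, re-scan and repair any unexpected background hit by
# mutating a base outside the planted intervals (a guard base can, rarely,
# complete a just-below-threshold background tract).
.verify_planted <- function(seq, contig, truth_contig, params,
                            max_iter = 50L) {
  key <- function(h) paste(h$start, h$stop, h$motif_class, h$unit,
                           ifelse(is.na(h$copies), "", h$copies))
  plant_iv <- truth_contig[, c("start", "stop"), drop = FALSE]
  in_plant <- function(j) any(j >= plant_iv$start & j <= plant_iv$stop)
  bases <- c("A", "C", "G", "T")
  for (iter in seq_len(max_iter)) {
    hits <- rbind(scan_zdna(seq, contig, params),
                  scan_str(seq, contig, params))
    unexpected <- hits[!key(hits) %in% key(truth_contig), , drop = FALSE]
    if (nrow(unexpected) == 0L) {
      missing <- truth_contig[!key(truth_contig) %in% key(hits), ,
                              drop = FALSE]
      if (nrow(missing) > 0L)
        stop("internal error: planted motif not recovered at ",
             missing$start[[1L]])
      return(seq)
    }
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    for (h in seq_len(nrow(unexpected))) {
      cand_pos <- unexpected$start[[h]]:unexpected$stop[[h]]
      cand_pos <- cand_pos[!vapply(cand_pos, in_plant, logical(1))]
      if (length(cand_pos) == 0L) next
      j <- cand_pos[[ceiling(length(cand_pos) / 2)]]
      avoid <- ch[[j]]
      for (u in params$str_unit_min:params$str_unit_max) {
        if (j - u >= 1L) avoid <- c(avoid, ch[[j - u]])
        if (j + u <= length(ch)) avoid <- c(avoid, ch[[j + u]])
      }
      cand <- setdiff(bases, avoid)
      if (length(cand) == 0L) cand <- setdiff(bases, ch[[j]])
      ch[[j]] <- sample(cand, 1L)
    }
    seq <- paste(ch, collapse = "")
  }
  stop("planted-genome repair did not converge after ", max_iter,
       " iterations")
}

# Choose a guard base for the flank of a planted payload.
.guard_base <- function(edge_base, periodic_partner, allow_at) {
  cand <- c("A", "C", "G", "T")
  cand <- cand[!.z_step_valid(cand, edge_base, allow_at)]
  cand <- setdiff(cand, periodic_partner)
  if (length(cand) == 0L)
    stop("no guard base available (unexpected payload edge)")
  sample(cand, 1L)
}

#' Simulate a genome with planted Z-DNA and STR motifs
#'
#' In `planted_only` mode the background is drawn at the requested GC
#' content and then scrubbed by rejection (re-drawing bases inside any
#' detected motif) until it contains no valid Z-DNA tract and no valid STR
#' under the active parameters; planted payloads are then inserted with
#' guard bases that prevent extension into the background, so the truth
#' table equals exactly what the scanners must report. In `oracle` mode the
#' background is left as drawn and the truth is the scan of the emitted
#' sequence. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return List with `sequences` (named character vector), `truth` (motif
#'   hit data frame) and `config`.
#' @seealso [write_fasta()], [write_motif_tsv()]
#' @export
sim_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  params <- config$params
  if (config$mode == "planted_only" &&
      (params$zdna_min_len < 6L || params$str_min_len < 8L ||
       params$str_min_copies < 3L || params$str_unit_min < 2L))
    stop("planted_only truth construction assumes zdna_min_len >= 6, ",
         "str_min_len >= 8, str_min_copies >= 3 and str_unit_min >= 2; ",
         "use mode = 'oracle' for more permissive thresholds")
  .with_seed(config$seed, {
    seqs <- character(0)
    truth_all <- list()
    for (contig in names(config$contig_lengths)) {
      clen <- config$contig_lengths[[contig]]
      n_plants <- config$n_zdna + config$n_str
      classes <- sample(c(rep("ZDNA", config$n_zdna),
                          rep("STR", config$n_str)))
      plants <- lapply(classes, .draw_plant, params = params)
      need <- sum(vapply(plants, function(p) nchar(p$payload), numeric(1))) +
        n_plants * 4L + 60L
      if (n_plants > 0L && need > clen)
        stop("requested plant density infeasible for contig length ", clen)
      seq <- .rand_dna(clen, config$gc)
      if (config$mode == "planted_only")
        seq <- .scrub_background(seq, contig, params)
      if (n_plants > 0L) {
        # evenly spaced slots with jitter, guards and >= 2 nt separation
        slot <- clen / n_plants
        ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
        cursor <- 0L
        for (i in seq_len(n_plants)) {
          p <- plants[[i]]
          plen <- nchar(p$payload)
          lo <- max(cursor + 3L, floor((i - 1L) * slot) + 3L)
          hi <- floor(i * slot) - plen - 3L
          if (hi < lo)
            stop("requested plant density infeasible for contig length ",
                 clen)
          pos <- sample(lo:hi, 1L)
          pay <- strsplit(p$payload, "", fixed = TRUE)[[1L]]
          ch[pos:(pos + plen - 1L)] <- pay
          u <- p$unit_len
          ch[[pos - 1L]] <- .guard_base(pay[[1L]],
                                        if (pos - 1L + u <= clen)
                                          ch[[pos - 1L + u]] else NULL,
                                        params$zdna_allow_at_steps)
          ch[[pos + plen]] <- .guard_base(pay[[plen]],
                                          if (pos + plen - u >= 1L)
                                            ch[[pos + plen - u]] else NULL,
                                          params$zdna_allow_at_steps)
          tr <- p$truth
          tr$start <- tr$start + pos - 1L
          tr$stop <- tr$stop + pos - 1L
          tr$seq_id <- contig
          truth_all[[length(truth_all) + 1L]] <- tr
          cursor <- pos + plen + 1L
        }
        seq <- paste(ch, collapse = "")
        if (config$mode == "planted_only") {
          tr_contig <- do.call(rbind, truth_all)
          tr_contig <- tr_contig[tr_contig$seq_id == contig, , drop = FALSE]
          seq <- .verify_planted(seq, contig, tr_contig, params)
        }
      }
      seqs[[contig]] <- seq
    }
    truth <- if (length(truth_all) > 0L) {
      t0 <- do.call(rbind, truth_all)
      t0 <- t0[, c("seq_id", "start", "stop", "length", "motif_class",
                   "unit", "copies", "sequence")]
      t0 <- t0[order(match(t0$seq_id, names(config$contig_lengths)),
                     t0$start, t0$motif_class, t0$stop, t0$unit),
               , drop = FALSE]
      rownames(t0) <- NULL
      t0
    } else .empty_hits()
    if (config$mode == "oracle") {
      truth <- do.call(rbind, lapply(names(seqs), function(id)
        rbind(scan_zdna(seqs[[id]], id, params),
              scan_str(seqs[[id]], id, params))))
      rownames(truth) <- NULL
    }
    list(sequences = seqs, truth = truth, config = config)
  })
}

#' Simulate a gene annotation with known upstream motif placements
#'
#' Generates `start_codon` (+ short `CDS`) features on both strands and
#' writes a matching truth table. With `placement` given, each row pairs a
#' motif from `motifs` with a requested distance bin; the gene's start
#' codon is positioned so that the motif's oriented anchor falls in that
#' bin of the upstream window.
#'
#' @param contig_lengths Named vector of contig lengths.
#' @param n_genes Number of genes (ignored when `placement` is given).
#' @param strand_mix Probability of the `+` strand.
#' @param seed RNG seed.
#' @param L Upstream window length (bp).
#' @param bin_bp Bin width (bp).
#' @param placement Optional data frame with columns `motif_row` (row index
#'   into `motifs`) and `bin` (requested bin index).
#' @param motifs Motif truth table (needed with `placement`).
#' @return List with `genes` (truth data frame: `gene_id`, `seq_id`,
#'   `strand`, `start_codon_pos`, `placed_bin`) and `gtf` (character vector
#'   of GTF lines).
#' @export
sim_annotation <- function(contig_lengths, n_genes = 20L, strand_mix = 0.5,
                           seed = 1L, L = 10000L, bin_bp = 1000L,
                           placement = NULL, motifs = NULL) {
  if (is.null(names(contig_lengths))) stop("contig_lengths must be named")
  .with_seed(seed, {
    rows <- list()
    if (is.null(placement)) {
      for (g in seq_len(n_genes)) {
        contig <- sample(names(contig_lengths), 1L)
        clen <- contig_lengths[[contig]]
        if (clen < 2L * L + 100L)
          stop("contig ", contig, " too short for a ", L, " bp window")
        strand <- if (stats::runif(1) < strand_mix) "+" else "-"
        pos <- sample((L + 40L):(clen - L - 40L), 1L)
        rows[[g]] <- data.frame(gene_id = sprintf("g%03d", g),
                                seq_id = contig, strand = strand,
                                start_codon_pos = pos,
                                placed_bin = NA_integer_,
                                stringsAsFactors = FALSE)
      }
    } else {
      if (is.null(motifs)) stop("placement requires the motif truth table")
      for (g in seq_len(nrow(placement))) {
        mi <- placement$motif_row[[g]]
        bin <- placement$bin[[g]]
        m <- motifs[mi, ]
        clen <- contig_lengths[[m$seq_id]]
        dist <- sample(((bin - 1L) * bin_bp + 1L):(bin * bin_bp), 1L)
        # pick a strand whose start codon (and short CDS) fits the contig;
        # truncated upstream windows are fine (they are kept downstream)
        plus_ok <- m$stop + dist + 40L <= clen
        minus_ok <- m$start - dist >= 40L
        strand <- if (plus_ok && minus_ok) {
          if (stats::runif(1) < strand_mix) "+" else "-"
        } else if (plus_ok) "+" else if (minus_ok) "-" else
          stop("placement infeasible for motif row ", mi, " bin ", bin)
        pos <- if (strand == "+") m$stop + dist else m$start - dist
        rows[[g]] <- data.frame(gene_id = sprintf("g%03d", g),
                                seq_id = m$seq_id, strand = strand,
                                start_codon_pos = as.integer(pos),
                                placed_bin = as.integer(bin),
                                stringsAsFactors = FALSE)
      }
    }
    genes <- do.call(rbind, rows)
    gtf <- unlist(lapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1";',
                       g$gene_id, g$gene_id)
      if (g$strand == "+") {
        sc <- c(g$start_codon_pos, g$start_codon_pos + 2L)
        cds <- c(g$start_codon_pos, g$start_codon_pos + 32L)
      } else {
        sc <- c(g$start_codon_pos - 2L, g$start_codon_pos)
        cds <- c(g$start_codon_pos - 32L, g$start_codon_pos)
      }
      c(paste(g$seq_id, "sim", "start_codon", sc[1L], sc[2L], ".",
              g$strand, "0", attrs, sep = "\t"),
        paste(g$seq_id, "sim", "CDS", cds[1L], cds[2L], ".",
              g$strand, "0", attrs, sep = "\t"))
    }))
    list(genes = genes, gtf = gtf)
  })
}

#' Simulate an ultrametric Yule (pure-birth) tree
#'
#' Starts from two lineages at the root; while `k` lineages are extant the
#' next speciation occurs after an exponential waiting time with rate
#' `k * birth_rate`, and a uniformly chosen lineage splits. After the n-th
#' tip appears, all tips are extended by one further exponential waiting
#' time (rate `n * birth_rate`), so the expected tree height is
#' `sum_{k=2}^{n} 1 / (k * birth_rate)`.
#'
#' @param n_tips Number of tips (>= 3).
#' @param birth_rate Speciation rate.
#' @param seed RNG seed.
#' @param tip_prefix Prefix for tip labels.
#' @return An ultrametric ape `phylo` tree with tips `t1..tn`.
#' @export
sim_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL,
                          tip_prefix = "t") {
  n_tips <- as.integer(n_tips)
  if (is.na(n_tips) || n_tips < 3L) stop("n_tips must be >= 3")
  if (!is.numeric(birth_rate) || birth_rate <= 0)
    stop("birth_rate must be > 0")
  .with_seed(seed, {
    n_internal <- n_tips - 1L
    parent_of <- integer(2L * n_tips - 1L)
    split_time <- numeric(2L * n_tips - 1L)
    next_internal <- n_tips + 1L
    root <- next_internal
    next_internal <- next_internal + 1L
    split_time[root] <- 0
    # active lineages: (parent internal id, birth time = parent split time)
    act_parent <- c(root, root)
    act_birth <- c(0, 0)
    t_now <- 0
    while (length(act_parent) < n_tips) {
      k <- length(act_parent)
      t_now <- t_now + stats::rexp(1L, rate = k * birth_rate)
      i <- sample.int(k, 1L)
      v <- next_internal
      next_internal <- next_internal + 1L
      parent_of[v] <- act_parent[[i]]
      split_time[v] <- t_now
      act_parent <- c(act_parent[-i], v, v)
      act_birth <- c(act_birth[-i], t_now, t_now)
    }
    t_now <- t_now + stats::rexp(1L, rate = n_tips * birth_rate)
    # remaining lineages become tips 1..n
    edges <- matrix(0L, nrow = 2L * n_tips - 2L, ncol = 2L)
    lens <- numeric(2L * n_tips - 2L)
    e <- 0L
    for (i in seq_along(act_parent)) {
      e <- e + 1L
      edges[e, ] <- c(act_parent[[i]], i)
      lens[[e]] <- t_now - act_birth[[i]]
    }
    for (v in setdiff((n_tips + 1L):(2L * n_tips - 1L), root)) {
      e <- e + 1L
      edges[e, ] <- c(parent_of[[v]], v)
      lens[[e]] <- split_time[[v]] - split_time[[parent_of[[v]]]]
    }
    tree <- structure(list(edge = edges, edge.length = lens,
                           tip.label = paste0(tip_prefix, seq_len(n_tips)),
                           Nnode = n_internal), class = "phylo")
    tree <- ape::reorder.phylo(tree, "cladewise")
    tree
  })
}

#' Simulate a continuous trait on a tree
#'
#' Draws one realization from the multivariate normal with mean `mu` and
#' covariance `sigma2 * V(model, shape)` built by [model_covariance()].
#'
#' @param tree An ape `phylo` tree.
#' @param model `"BM"`, `"OU"`, `"EB"` or `"lambda"`.
#' @param sigma2 Rate parameter (>= 0).
#' @param mu Root state / mean.
#' @param shape Shape parameter for non-BM models.
#' @param seed RNG seed.
#' @return Named trait vector over the tips.
#' @export
sim_trait <- function(tree, model = "BM", sigma2 = 1, mu = 0,
                      shape = NULL, seed = NULL) {
  .check_tree(tree)
  if (!is.numeric(sigma2) || sigma2 < 0) stop("sigma2 must be >= 0")
  n <- length(tree$tip.label)
  if (sigma2 == 0) {
    x <- rep(mu, n); names(x) <- tree$tip.label
    return(x)
  }
  V <- model_covariance(tree, model, shape)
  U <- chol(sigma2 * V)
  .with_seed(seed, {
    x <- mu + drop(crossprod(U, stats::rnorm(n)))
    names(x) <- tree$tip.label
    x
  })
}

#' Simulate a phylogenetic regression dataset
#'
#' Builds `y = beta[1] + beta[2] * x + e` with `e` multivariate normal,
#' covariance `sigma2 * V(model, shape)` on the tree. When `x` is `NULL` a
#' Brownian-motion predictor (unit rate) is drawn first.
#'
#' @param tree An ape `phylo` tree.
#' @param x Optional named predictor vector.
#' @param beta Length-2 coefficient vector (intercept, slope).
#' @param model,sigma2,shape Residual covariance model (see [sim_trait()]).
#' @param seed RNG seed.
#' @return List with named vectors `x` and `y`.
#' @export
sim_regression_dataset <- function(tree, x = NULL, beta = c(0, 0.5),
                                   model = "BM", sigma2 = 1, shape = NULL,
                                   seed = NULL) {
  .check_tree(tree)
  if (length(beta) != 2L) stop("beta must be (intercept, slope)")
  .with_seed(seed, {
    if (is.null(x)) {
      x <- sim_trait(tree, "BM", sigma2 = 1)
    } else {
      x <- .align_trait(tree, x)
    }
    e <- sim_trait(tree, model, sigma2 = sigma2, shape = shape)
    y <- beta[[1L]] + beta[[2L]] * x + e
    names(y) <- tree$tip.label
    list(x = x, y = y)
  })
}
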