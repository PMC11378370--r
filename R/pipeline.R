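## induced pair restricted to a set of alignment columns
induce_pair_cols <- function(aln, node_a, node_b, cols) {
  ca <- chars(aln[[node_a]])[cols]
  cb <- chars(aln[[node_b]])[cols]
  keep <- !(ca == "-" & cb == "-")
  structure(list(a = paste(ca[keep], collapse = ""),
                 b = paste(cb[keep], collapse = ""),
                 cols = cols[keep]),
            class = "induced_pair")
}

most_upstream <- function(orfs) {
  if (nrow(orfs) == 0) NULL else orfs[1, , drop = FALSE]
}

## does an ORF's segment carry a start under a Kozak rule?
segment_has_pattern <- function(context, orf, rule) {
  if (is.null(orf)) return(NA)
  !is.na(locate_start(context, orf$seg_start, orf$seg_end, rule))
}

## feature row for one locus on one birth edge
locus_edge_features <- function(aug, locus, parent, child) {
  cerc <- chars(aug[["cerevisiae"]])
  cer_cols <- which(cerc != "-")
  gr <- gene_region(locus)
  gcols <- cer_cols[gr[1]:gr[2]]

  child_row <- chars(aug[[child]])
  child_pos <- which(child_row != "-")
  child_seq <- paste(child_row[child_pos], collapse = "")
  in_region <- which(child_pos >= min(gcols) & child_pos <= max(gcols))
  child_region <- if (length(in_region)) range(in_region) else c(1L, 0L)

  parent_row <- chars(aug[[parent]])
  parent_pos <- which(parent_row != "-")
  parent_seq <- paste(parent_row[parent_pos], collapse = "")

  pair_region <- induce_pair_cols(aug, parent, child, gcols)
  mut <- classify_mutations(pair_region)

  anc_region <- degap(paste(parent_row[gcols], collapse = ""))
  rec_region <- degap(paste(child_row[gcols], collapse = ""))
  gc_anc <- if (nzchar(anc_region)) gc_content(anc_region, "nongenic") else NA_real_
  gc_rec <- if (!nzchar(rec_region)) NA_real_
            else if (nchar(rec_region) %% 3 == 0) gc_content(rec_region, "genic")
            else gc_content(rec_region, "nongenic")

  pair_full <- induce_pair(aug, parent, child)

  row <- list(id = locus$entry$id, class = locus$entry$class,
              edge = paste0(parent, "->", child),
              gc_anc = gc_anc, gc_rec = gc_rec)
  for (cl in MUTATION_CLASSES)
    row[[paste0("freq_", gsub("[>+]", "_", cl))]] <- unname(mut$freqs[cl])
  row$n_sub_cols <- unname(mut$denominators["sub"])

  for (rule in START_RULES) {
    key <- c(ATG = "atg", `A..ATG` = "a_atg", `A..ATG.C` = "a_atg_c")[[rule]]
    rec <- if (child_region[1] <= child_region[2])
      most_upstream(scan_orfs(child_seq, rule, region = child_region)) else NULL
    anc <- if (!is.null(rec)) map_ancestral_orf(rec, pair_full, rule) else NULL
    row[[paste0("orf_len_rec_", key)]] <-
      if (is.null(rec)) NA_integer_ else rec$length
    row[[paste0("orf_len_anc_", key)]] <-
      if (is.null(anc)) NA_integer_ else anc$length
    row[[paste0("change_", key)]] <-
      if (is.null(rec)) NA_character_ else classify_length_change(anc, rec)
  }

  rec_atg <- if (child_region[1] <= child_region[2])
    most_upstream(scan_orfs(child_seq, "ATG", region = child_region)) else NULL
  anc_atg <- if (!is.null(rec_atg)) map_ancestral_orf(rec_atg, pair_full, "ATG") else NULL
  for (rule in c("A..ATG", "A..ATG.C")) {
    key <- if (rule == "A..ATG") "a_atg" else "a_atg_c"
    rh <- segment_has_pattern(child_seq, rec_atg, rule)
    ah <- segment_has_pattern(parent_seq, anc_atg, rule)
    row[[paste0("kozak_", key)]] <-
      if (is.na(rh) || is.na(ah)) NA_character_ else classify_kozak_transition(ah, rh)
  }
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Run the de novo gene-birth scenario analysis
#'
#' The full pipeline: filter the catalogue by minimum ORF length, extract
#' each locus with flanks from the focal genome, map its best orthologous
#' region in each related genome by glocal alignment, build a progressive
#' multiple alignment, reconstruct marginal ML ancestral sequences at A1
#' and A2, apply the confidence filter, compute the per-locus feature set
#' on the class's birth edge (intergene loci on both edges, as the neutral
#' background), and pool the per-class statistics into the four-stage
#' scenario report.
#'
#' @param genomes named list of genomes (species -> named chromosome
#'   vector); must contain `cerevisiae`, `paradoxus` and `mikatae`
#'   (`bayanus` optional).
#' @param catalogue catalogue data frame (see [read_catalogue()]).
#' @param tree species tree (see [tree_info()]).
#' @param flank flank length extracted around each locus, nt (default 500).
#' @param min_orf_len minimum catalogued ORF length kept, nt (default 60).
#' @param confidence ancestral-sequence confidence threshold (default 0.80).
#' @param scoring a [scoring_scheme()].
#' @param model a [sub_model()] for the reconstruction.
#' @param score_floor passed to [find_orthologue()].
#' @param alpha significance level for the report.
#' @param verbose print per-locus progress.
#' @return object of class `denovo_scenario`: list with `features` (one row
#'   per locus x edge), `summaries` (`gc`, `mutations`, `orf_changes`,
#'   `kozak`), `tests`, `report`, `log` (per-stage counts and per-locus
#'   drop reasons), `params`.
#' @export
denovo_scenario <- function(genomes, catalogue, tree = yeast_tree(),
                            flank = 500, min_orf_len = 60, confidence = 0.80,
                            scoring = scoring_scheme(), model = sub_model(),
                            score_floor = NULL, alpha = 0.01,
                            verbose = FALSE) {
  if (!"cerevisiae" %in% names(genomes))
    stop("genomes must include the focal species 'cerevisiae'")
  ti <- tree_info(tree)
  related <- genomes[setdiff(intersect(names(genomes), ti$leaves), "cerevisiae")]
  validate_catalogue(catalogue)

  kept <- filter_catalogue(catalogue, min_orf_len)
  discarded <- attr(kept, "discarded")
  drops <- data.frame(id = character(), stage = character(),
                      reason = character(), stringsAsFactors = FALSE)
  feats <- list()

  for (i in seq_len(nrow(kept))) {
    entry <- kept[i, ]
    if (!entry$class %in% c("S0+", "S1", "S2", "intergene")) {
      drops <- rbind(drops, data.frame(id = entry$id, stage = "assign_edge",
                                       reason = "unsupported class"))
      next
    }
    locus <- extract_locus(genomes[["cerevisiae"]], entry, flank)
    ortho <- find_orthologue(locus, related, scoring, score_floor)
    have <- names(ortho$hits)[!vapply(ortho$hits, is.null, TRUE)]
    if (!all(c("paradoxus", "mikatae") %in% have)) {
      drops <- rbind(drops, data.frame(id = entry$id, stage = "map",
                                       reason = "missing orthologue"))
      next
    }
    seqs <- c(list(cerevisiae = locus$sequence),
              lapply(ortho$hits[have], `[[`, "sequence"))
    msa <- build_msa(seqs, guide = ti$tree, scoring = scoring)
    anc <- reconstruct_ancestors(msa, ti$tree, model)
    aug <- c(unclass(msa),
             setNames(vapply(anc, `[[`, "", "sequence"), names(anc)))

    edges <- if (entry$class %in% c("S0+", "S1")) {
      list(assign_birth_edge(entry$class, ti$tree))
    } else if (entry$class == "S2") {
      list(assign_birth_edge("S2", ti$tree))
    } else {
      list(assign_birth_edge("S0+", ti$tree), assign_birth_edge("S2", ti$tree))
    }
    for (e in edges) {
      needed <- intersect(c(e$parent, e$child), names(anc))
      confs <- vapply(anc[needed], `[[`, 1, "confidence")
      if (any(is.na(confs)) || any(confs < confidence)) {
        drops <- rbind(drops, data.frame(
          id = entry$id, stage = "confidence",
          reason = paste0("low confidence on ", e$parent, "->", e$child)))
        next
      }
      feats[[length(feats) + 1L]] <- locus_edge_features(aug, locus, e$parent, e$child)
    }
    if (verbose) message(entry$id, " done")
  }

  features <- if (length(feats)) do.call(rbind, feats) else NULL
  res <- pool_scenario(features, alpha = alpha, a1 = ti$a1_label,
                       a2 = ti$a2_label)
  log <- list(n_catalogue = nrow(catalogue),
              n_after_length_filter = nrow(kept),
              discarded_by_length = discarded,
              drops = drops,
              n_feature_rows = if (is.null(features)) 0L else nrow(features))
  structure(list(features = features, summaries = res$summaries,
                 tests = res$tests, report = res$report, log = log,
                 params = list(flank = flank, min_orf_len = min_orf_len,
                               confidence = confidence, scoring = scoring,
                               model = model, alpha = alpha)),
            class = "denovo_scenario")
}

## pooled summaries + tests + report from a feature table
pool_scenario <- function(features, alpha = 0.01, a1 = "A1", a2 = "A2") {
  if (is.null(features) || nrow(features) == 0)
    return(list(summaries = NULL, tests = NULL, report = NULL))
  freq_cols <- paste0("freq_", gsub("[>+]", "_", MUTATION_CLASSES))
  edge_of_class <- function(cls) {
    if (cls %in% c("S0+", "S1")) paste0(a1, "->cerevisiae")
    else paste0(a2, "->", a1)
  }
  classes <- intersect(c("S0+", "S1", "S2"), unique(features$class))

  summ <- function(x) {
    x <- x[!is.na(x)]
    c(n = length(x), ave = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA)
  }
  gc_rows <- list(); mut_rows <- list(); orf_rows <- list(); koz_rows <- list()
  gc_tests <- list(); mut_tests <- list(); orf_tests <- list(); koz_tests <- list()
  rule_keys <- c(atg = "ATG", a_atg = "A..ATG", a_atg_c = "A..ATG.C")

  for (cls in c(classes, "intergene")) {
    for (edge in unique(features$edge[features$class == cls])) {
      sel <- features$class == cls & features$edge == edge
      s <- summ(features$gc_anc[sel])
      gc_rows[[length(gc_rows) + 1L]] <- data.frame(
        region = cls, edge = edge, node = "ancestor", n = s["n"],
        ave = s["ave"], sd = s["sd"])
      s2 <- summ(features$gc_rec[sel])
      gc_rows[[length(gc_rows) + 1L]] <- data.frame(
        region = cls, edge = edge, node = "descendant", n = s2["n"],
        ave = s2["ave"], sd = s2["sd"])
      for (fc in freq_cols) {
        s3 <- summ(features[[fc]][sel])
        mut_rows[[length(mut_rows) + 1L]] <- data.frame(
          region = cls, edge = edge, mutation = fc, n = s3["n"],
          ave = s3["ave"], sd = s3["sd"])
      }
      for (k in names(rule_keys)) {
        tab <- table(factor(features[[paste0("change_", k)]][sel],
                            levels = c("Extend", "Shrink", "NoChange")))
        orf_rows[[length(orf_rows) + 1L]] <- data.frame(
          region = cls, edge = edge, rule = rule_keys[[k]],
          extend = tab["Extend"], shrink = tab["Shrink"],
          no_change = tab["NoChange"],
          unmapped = sum(sel & is.na(features[[paste0("change_", k)]])))
      }
      for (k in c("a_atg", "a_atg_c")) {
        tab <- table(factor(features[[paste0("kozak_", k)]][sel],
                            levels = c("No", "Retain", "Disappear", "Appear")))
        koz_rows[[length(koz_rows) + 1L]] <- data.frame(
          region = cls, edge = edge, rule = rule_keys[[k]],
          no = tab["No"], retain = tab["Retain"],
          disappear = tab["Disappear"], appear = tab["Appear"])
      }
    }
  }
  summaries <- list(gc = do.call(rbind, gc_rows),
                    mutations = do.call(rbind, mut_rows),
                    orf_changes = do.call(rbind, orf_rows),
                    kozak = do.call(rbind, koz_rows))
  for (s in names(summaries)) rownames(summaries[[s]]) <- NULL

  has_bg <- "intergene" %in% features$class
  for (cls in classes) {
    edge <- edge_of_class(cls)
    sel <- features$class == cls & features$edge == edge
    bg <- features$class == "intergene" & features$edge == edge
    if (!any(sel) || !has_bg || sum(bg) < 2 || sum(sel) < 2) next
    gv <- features$gc_anc[sel]; bv <- features$gc_anc[bg]
    if (sum(!is.na(gv)) >= 2 && sum(!is.na(bv)) >= 2)
      gc_tests[[cls]] <- welch_test(gv[!is.na(gv)], bv[!is.na(bv)])
    mt <- list()
    for (fc in freq_cols) {
      xv <- features[[fc]][sel]; yv <- features[[fc]][bg]
      if (sum(!is.na(xv)) >= 2 && sum(!is.na(yv)) >= 2)
        mt[[fc]] <- welch_test(xv[!is.na(xv)], yv[!is.na(yv)])
    }
    if (length(mt)) mut_tests[[cls]] <- mt
    for (k in names(rule_keys)) {
      ch <- features[[paste0("change_", k)]]
      ke <- sum(ch[sel] == "Extend", na.rm = TRUE)
      ks <- sum(ch[sel] == "Shrink", na.rm = TRUE)
      be <- sum(ch[bg] == "Extend", na.rm = TRUE)
      bs <- sum(ch[bg] == "Shrink", na.rm = TRUE)
      if (ke + ks >= 1)
        orf_tests[[paste(cls, rule_keys[[k]])]] <-
          binomial_trend_test(ke, ks, c(extend = be, shrink = bs))
    }
    for (k in c("a_atg", "a_atg_c")) {
      kz <- features[[paste0("kozak_", k)]]
      ka <- sum(kz[sel] == "Appear", na.rm = TRUE)
      kd <- sum(kz[sel] == "Disappear", na.rm = TRUE)
      ba <- sum(kz[bg] == "Appear", na.rm = TRUE)
      bd <- sum(kz[bg] == "Disappear", na.rm = TRUE)
      if (ka + kd >= 1)
        koz_tests[[paste(cls, rule_keys[[k]])]] <-
          kozak_trend_test(ka, kd, c(appear = ba, disappear = bd))
    }
  }
  tests <- list(gc = gc_tests, mutations = mut_tests,
                orf_changes = orf_tests, kozak = koz_tests)
  report <- tryCatch(
    build_report(gc_tests, mut_tests, orf_tests, koz_tests, alpha = alpha),
    error = function(e) NULL)
  list(summaries = summaries, tests = tests, report = report)
}

#' @export
print.denovo_scenario <- function(x, ...) {
  cat("De novo gene-birth scenario analysis\n")
  cat("  catalogue: ", x$log$n_catalogue, " loci, ",
      x$log$n_after_length_filter, " after length filter, ",
      x$log$n_feature_rows, " feature rows\n", sep = "")
  if (!is.null(x$report)) print(x$report)
  else cat("  (insufficient data for a scenario report)\n")
  invisible(x)
}

#' @export
summary.denovo_scenario <- function(object, ...) {
  print(object)
  if (!is.null(object$summaries)) {
    cat("\nAncestral/descendant GC by class:\n")
    print(object$summaries$gc, digits = 3)
    cat("\nORF length changes:\n")
    print(object$summaries$orf_changes)
  }
  invisible(object)
}

#' @export
plot.denovo_scenario <- function(x, ...) {
  if (is.null(x$features)) {
    warning("nothing to plot")
    return(invisible(x))
  }
  f <- x$features
  grp <- interaction(f$class, ifelse(grepl("cerevisiae", f$edge), "A1-edge", "A2-edge"),
                     drop = TRUE)
  graphics::boxplot(f$gc_anc ~ grp, ylab = "ancestral GC fraction",
                    xlab = "", las = 2, ...)
  invisible(x)
}

#' Run the pipeline from a configuration and write its artifacts
#'
#' Thin orchestration over [denovo_scenario()]: reads genomes, catalogue
#' and tree from paths (or takes a [simulate_catalogue()] result directly),
#' runs the analysis, and optionally writes `features.tsv`, the four
#' summary tables, `scenario_report.json` and `log.tsv` to `out_dir`.
#' Everything is deterministic given the inputs.
#'
#' @param config either a `gene_birth_sim` object, or a list (or YAML file
#'   path) with `genomes` (dir with `<species>.fa` or named paths),
#'   `catalogue`, `tree`, and optionally `flank`, `min_orf_len`,
#'   `confidence`, `kappa`, `score_floor`, `alpha`.
#' @param out_dir output directory, or NULL for no files.
#' @return the `denovo_scenario` object, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (inherits(config, "gene_birth_sim")) {
    genomes <- config$genomes
    catalogue <- config$catalogue
    tree <- config$tree
    opts <- list()
  } else {
    if (is.character(config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the 'yaml' package")
      config <- yaml::read_yaml(config)
    }
    gp <- config$genomes
    if (length(gp) == 1 && dir.exists(gp)) {
      files <- list.files(gp, pattern = "\\.fa(sta)?$", full.names = TRUE)
      gp <- setNames(files, sub("\\.fa(sta)?$", "", basename(files)))
    }
    genomes <- lapply(gp, read_genome)
    catalogue <- read_catalogue(config$catalogue)
    tree <- config$tree
    opts <- config
  }
  get <- function(key, default) if (!is.null(opts[[key]])) opts[[key]] else default
  scen <- denovo_scenario(
    genomes, catalogue, tree,
    flank = get("flank", 500),
    min_orf_len = get("min_orf_len", 60),
    confidence = get("confidence", 0.80),
    model = sub_model(kappa = get("kappa", 2)),
    score_floor = get("score_floor", NULL),
    alpha = get("alpha", 0.01))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, name) if (!is.null(df))
      write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    w(scen$features, "features.tsv")
    w(scen$summaries$gc, "summary_gc.tsv")
    w(scen$summaries$mutations, "summary_mutations.tsv")
    w(scen$summaries$orf_changes, "summary_orf_changes.tsv")
    w(scen$summaries$kozak, "summary_kozak.tsv")
    w(scen$log$drops, "log.tsv")
    if (!is.null(scen$report))
      jsonlite::write_json(
        lapply(scen$report$stages, function(s)
          list(stage = s$stage, label = s$label, statistic = s$statistic,
               p = as.list(s$p), supported = s$supported)),
        file.path(out_dir, "scenario_report.json"), auto_unbox = TRUE,
        digits = NA)
  }
  invisible(scen)
}
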