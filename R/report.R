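# One-shot report: run the full battery (composition -> RSCU -> ENC /
# neutrality -> adaptation -> dinucleotides -> PCA) over a FASTA input and
# emit a tidy results bundle: one TSV per module (3-decimal printing), a
# machine-readable summary JSON at full precision, and a run log.  The
# bundle is deterministic given the resolved configuration and seed
# (timestamps live only in the log file, never in the summary).

.default_thresholds <- function() {
  list(rscu_over = 1.6, rscu_under = 0.6,
       dinuc_over = 1.23, dinuc_under = 0.78,
       enc_bias = 35)
}

.round_df <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

.write_tsv <- function(df, path, digits = 3) {
  utils::write.table(.round_df(df, digits), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                        force = TRUE, null = "null")
  h <- 5381
  for (k in utf8ToInt(as.character(s))) h <- (h * 33 + k) %% 16777216
  sprintf("%06x", h)
}

#' Run the full codon-usage analysis battery
#'
#' @param input FASTA path (or a list of `cub_cds`).
#' @param out_dir output directory, created if needed.
#' @param hosts character names or paths resolvable by
#'   [load_host_reference()], or a list of `cub_host`; `NULL` skips the
#'   adaptation block.
#' @param groups optional grouping: a two-column data.frame (id, group) or
#'   the path of such a TSV.  Group-level RSCU (both pooled-count and
#'   mean-of-sequence, labelled), neutrality fits, SiD and
#'   coincidence/antagonism reports are emitted per group; ungrouped runs
#'   treat the whole input as one group `"all"`.
#' @param thresholds named list overriding the default representation
#'   thresholds (RSCU 1.6/0.6, dinucleotide odds 1.23/0.78, ENC strong-bias
#'   cutoff 35).
#' @param circular use circular dinucleotide counting.
#' @param seed integer seed recorded in the config (the battery itself is
#'   deterministic).
#' @param verbose print progress to stderr.
#' @return Invisibly, the list of result tables plus `summary` (the
#'   object written as `summary.json`).
#' @export
run_report <- function(input, out_dir, hosts = c("sus_scrofa",
                                                 "sus_scrofa_domestica"),
                       groups = NULL, thresholds = list(), circular = FALSE,
                       seed = 1L, verbose = FALSE) {
  thr <- utils::modifyList(.default_thresholds(), thresholds)
  say <- function(...) if (verbose) message("[cubkit] ", ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.character(input)) {
    seqs <- read_fasta(input, on_invalid = "skip")
  } else {
    seqs <- input
    attr(seqs, "failures") <- attr(seqs, "failures") %||%
      data.frame(id = character(), reason = character())
  }
  if (length(seqs) == 0L) stop("run_report: no valid sequences in input")
  ids <- vapply(seqs, `[[`, "", "id")

  if (is.character(groups)) groups <- utils::read.delim(groups,
                                                        stringsAsFactors = FALSE)
  grp <- if (is.null(groups)) stats::setNames(rep("all", length(seqs)), ids)
  else {
    g <- stats::setNames(as.character(groups[[2L]]),
                         as.character(groups[[1L]]))
    stats::setNames(ifelse(is.na(g[ids]), "ungrouped", g[ids]), ids)
  }

  host_refs <- if (is.null(hosts)) list() else if (is.character(hosts))
    lapply(hosts, load_host_reference) else hosts

  say("composition")
  comp <- composition_batch(seqs)
  .write_tsv(comp, file.path(out_dir, "composition.tsv"))

  say("RSCU")
  profs <- rscu_batch(seqs)
  rscu_tab <- data.frame(id = ids,
                         do.call(rbind, lapply(profs, unclass)),
                         stringsAsFactors = FALSE, check.names = FALSE)
  .write_tsv(rscu_tab, file.path(out_dir, "rscu.tsv"))

  say("ENC / neutrality")
  encs <- enc_batch(seqs)
  encs$strong_bias <- encs$enc < thr$enc_bias
  .write_tsv(encs, file.path(out_dir, "enc.tsv"))

  neut <- list()
  for (g in unique(grp)) {
    sub <- encs[grp[encs$id] == g, , drop = FALSE]
    fit <- tryCatch(neutrality_fit(sub), error = function(e) e)
    neut[[g]] <- if (inherits(fit, "error"))
      list(error = conditionMessage(fit), n = nrow(sub))
    else fit[c("slope", "intercept", "r_squared", "p_value",
               "pct_mutation", "pct_selection", "n")]
  }
  neut_df <- do.call(rbind, lapply(names(neut), function(g) {
    x <- neut[[g]]
    if (!is.null(x$error))
      data.frame(group = g, slope = NA_real_, intercept = NA_real_,
                 r_squared = NA_real_, p_value = NA_real_,
                 pct_mutation = NA_real_, pct_selection = NA_real_,
                 n = x$n, stringsAsFactors = FALSE)
    else cbind(data.frame(group = g, stringsAsFactors = FALSE),
               as.data.frame(x))
  }))
  .write_tsv(neut_df, file.path(out_dir, "neutrality.tsv"))

  say("dinucleotides")
  dinuc <- dinucleotide_batch(seqs, mode = if (circular) "circular"
                              else "linear",
                              over = thr$dinuc_over, under = thr$dinuc_under)
  .write_tsv(dinuc, file.path(out_dir, "dinucleotide.tsv"))

  adapt <- NULL
  sid_rows <- list()
  coin <- list()
  group_rscu <- list()
  for (g in unique(grp)) {
    members <- profs[grp == g]
    group_rscu[[g]] <- list(
      mean_of_sequences = mean_rscu(members),
      pooled_counts = pooled_rscu(seqs[grp == g]))
  }
  if (length(host_refs)) {
    say("adaptation (CAI / RCDI / SiD)")
    adapt <- adaptation_batch(seqs, host_refs)
    .write_tsv(adapt, file.path(out_dir, "adaptation.tsv"))
    for (g in names(group_rscu)) {
      gp <- group_rscu[[g]]$mean_of_sequences
      for (h in host_refs) {
        s <- tryCatch(sid(gp, h), error = function(e) NULL)
        cr <- tryCatch(coincidence_analysis(gp, h$rscu),
                       error = function(e) NULL)
        sid_rows[[paste(g, h$name, sep = "|")]] <-
          data.frame(group = g, host = h$name,
                     R = if (is.null(s)) NA_real_ else s$R,
                     sid = if (is.null(s)) NA_real_ else s$D,
                     stringsAsFactors = FALSE)
        if (!is.null(cr))
          coin[[paste(g, h$name, sep = "|")]] <- list(
            group = g, host = h$name,
            n_coincidence = cr$n_coincidence,
            n_antagonism = cr$n_antagonism,
            ending_census = as.list(cr$ending_census))
      }
    }
    if (length(sid_rows))
      .write_tsv(do.call(rbind, sid_rows), file.path(out_dir, "sid.tsv"))
  }

  pca <- NULL
  if (length(profs) >= 2L) {
    say("PCA")
    pca <- tryCatch(pca_rscu(profs), error = function(e) NULL,
                    warning = function(w) NULL)
    if (!is.null(pca)) {
      pca_tab <- data.frame(id = rownames(pca$coordinates),
                            group = unname(grp[rownames(pca$coordinates)]),
                            pca$coordinates, stringsAsFactors = FALSE)
      .write_tsv(pca_tab, file.path(out_dir, "pca.tsv"))
    }
  }

  over_calls <- lapply(group_rscu, function(gl)
    names(which(representation_calls(gl$mean_of_sequences,
                                     over = thr$rscu_over,
                                     under = thr$rscu_under) == "over")))

  config <- list(n_input = length(seqs) + nrow(attr(seqs, "failures")),
                 hosts = vapply(host_refs, `[[`, "", "name"),
                 groups = unname(grp), thresholds = thr,
                 circular = circular, seed = seed)
  summary <- list(
    tool = "cubkit", version = as.character(utils::packageVersion("cubkit")),
    config_hash = .config_hash(config),
    thresholds = thr,
    n_sequences = length(seqs),
    failures = attr(seqs, "failures"),
    enc = list(mean = mean(encs$enc), sd = stats::sd(encs$enc),
               n_strong_bias = sum(encs$strong_bias),
               n_below_curve = sum(encs$below_curve)),
    neutrality = neut,
    over_represented = over_calls,
    sid = if (length(sid_rows)) do.call(rbind, sid_rows) else NULL,
    coincidence = coin,
    pca_explained_variance_pct = if (!is.null(pca))
      pca$explained_variance_pct[seq_len(pca$n_axes)] else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE, force = TRUE)
  writeLines(c(
    sprintf("cubkit %s", summary$version),
    sprintf("time: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("config hash: %s", summary$config_hash),
    sprintf("input sequences: %d valid, %d invalid", length(seqs),
            nrow(attr(seqs, "failures"))),
    sprintf("hosts: %s", paste(config$hosts, collapse = ", ")),
    sprintf("thresholds: rscu %s/%s dinuc %s/%s enc_bias %s",
            thr$rscu_over, thr$rscu_under, thr$dinuc_over,
            thr$dinuc_under, thr$enc_bias)
  ), file.path(out_dir, "run.log"))
  invisible(list(composition = comp, rscu = rscu_tab, enc = encs,
                 neutrality = neut_df, dinucleotide = dinuc,
                 adaptation = adapt, pca = pca, summary = summary))
}
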