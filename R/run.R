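# Pipeline commands backing the CLI: each run_*() is a plain function over
# the package's building blocks, writes text artifacts that embed the
# config hash, and returns its main result invisibly usable from R too.

write_csv_artifact <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", cfg$hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_artifact <- function(path) {
  if (!file.exists(path)) abort_input(paste0("file not found: ", path))
  as_tibble(utils::read.csv(path, comment.char = "#", check.names = FALSE))
}

#' Extract PseAAC features for a FASTA file
#'
#' For every sequence, locates its evolutionary profile — `<id>.pssm`
#' (PSI-BLAST ASCII) in `profiles`, or `<id>.fasta`/`<id>.afa` alignment in
#' `msa` (converted to a profile with BLOSUM62 pseudo-counts) — collapses
#' it to the profile-consensus sequence and computes PseAAC features. When
#' neither directory holds a match the sequence itself is not silently
#' used: it is reported in the sidecar failure file and the run aborts
#' unless `permissive`.
#'
#' @param fasta Path to the input FASTA.
#' @param profiles,msa Optional directories of per-sequence profiles or
#'   alignments.
#' @param config A [run_config()].
#' @param out Optional path for the feature CSV; failures go to
#'   `<out>.failures.tsv`.
#' @param permissive Continue past per-sequence failures.
#' @return The feature tibble, invisibly when `out` is given.
#' @export
run_extract <- function(fasta, profiles = NULL, msa = NULL,
                        config = run_config(), out = NULL, permissive = FALSE) {
  seqs <- read_fasta(fasta)
  props <- config_properties(config)
  failures <- list()
  cons <- purrr::map2(seqs$id, seqs$residues, function(id, s) {
    tryCatch({
      prof <- locate_profile(id, profiles, msa)
      if (is.null(prof)) {
        abort_input(paste0("no profile or alignment found for ", id))
      }
      consensus_sequence(prof)
    }, error = function(e) {
      failures[[id]] <<- conditionMessage(e)
      NULL
    })
  })
  ok <- !purrr::map_lgl(cons, is.null)
  if (length(failures) > 0) {
    fail_df <- data.frame(seq_id = names(failures),
                          reason = unlist(failures))
    if (!is.null(out)) {
      utils::write.table(fail_df, paste0(out, ".failures.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    if (!permissive) {
      abort_input(paste0("feature extraction failed for: ",
                         paste(names(failures), collapse = ", ")))
    }
    warn(paste0("skipping ", length(failures), " sequence(s); see sidecar report."))
  }
  features <- featurize_batch(cons[ok], lambda = config$lambda,
                              omega = config$omega, props = props,
                              permissive = permissive)
  if (!is.null(out)) {
    write_csv_artifact(as.data.frame(features), out, config)
    return(invisible(features))
  }
  features
}

locate_profile <- function(id, profiles, msa) {
  if (!is.null(profiles)) {
    f <- file.path(profiles, paste0(id, ".pssm"))
    if (file.exists(f)) return(read_psiblast_pssm(f, seq_id = id))
  }
  if (!is.null(msa)) {
    for (ext in c(".fasta", ".afa", ".fa")) {
      f <- file.path(msa, paste0(id, ext))
      if (file.exists(f)) {
        aln <- read_alignment(f)
        return(apply_pseudocounts(observed_profile(aln, seq_id = id)))
      }
    }
  }
  NULL
}

# Labels for a feature tibble: either an embedded `label` column or a
# two-column (seq_id, label) TSV manifest.
resolve_labels <- function(features, labels_path = NULL) {
  if (!is.null(labels_path)) {
    lab <- utils::read.delim(labels_path)
    if (!all(c("seq_id", "label") %in% names(lab))) {
      abort_input("label manifest needs columns `seq_id` and `label`.")
    }
    idx <- match(features$seq_id, lab$seq_id)
    if (any(is.na(idx))) {
      abort_input(paste0("no label for: ",
                         paste(features$seq_id[is.na(idx)], collapse = ", ")))
    }
    return(normalize_labels(lab$label[idx]))
  }
  if (!"label" %in% names(features)) {
    abort_input("no `label` column and no label manifest given.")
  }
  normalize_labels(features$label)
}

#' Train a model from a feature CSV
#'
#' @param features_csv Feature CSV from [run_extract()] (or a feature
#'   tibble); labels come from an embedded `label` column or `labels` TSV.
#' @param labels Optional path to a `seq_id`/`label` TSV manifest.
#' @param config A [run_config()].
#' @param out Path for the JSON model archive.
#' @return The fitted `pseaac_svm`, invisibly when `out` is given.
#' @export
run_train <- function(features_csv, labels = NULL, config = run_config(),
                      out = NULL) {
  features <- if (is.data.frame(features_csv)) features_csv
              else read_csv_artifact(features_csv)
  y <- resolve_labels(features, labels)
  props <- config_properties(config)
  model <- svm_train(features, y, C = config$C, gamma = config$gamma,
                     meta = list(lambda = config$lambda, omega = config$omega,
                                 property_hash = property_hash(props),
                                 config_hash = config$hash))
  if (!is.null(out)) {
    write_model(model, out)
    return(invisible(model))
  }
  model
}

#' Predict with a stored model
#'
#' @param model_path Path to a [write_model()] archive (or a `pseaac_svm`).
#' @param features_csv Feature CSV or tibble.
#' @param config A [run_config()].
#' @param out Optional CSV path for the predictions.
#' @return Tibble with `seq_id`, `decision`, `prob`, `label`.
#' @export
run_predict <- function(model_path, features_csv, config = run_config(),
                        out = NULL) {
  model <- if (inherits(model_path, "pseaac_svm")) model_path
           else read_model(model_path)
  features <- if (is.data.frame(features_csv)) features_csv
              else read_csv_artifact(features_csv)
  res <- tibble(
    seq_id = if ("seq_id" %in% names(features)) features$seq_id
             else as.character(seq_len(nrow(features))),
    decision = predict(model, features, type = "decision"),
    prob = predict(model, features, type = "probability"),
    label = predict(model, features, type = "class")
  )
  if (!is.null(out)) {
    write_csv_artifact(as.data.frame(res), out, config)
    return(invisible(res))
  }
  res
}

#' Jackknife-evaluate a labeled feature set
#'
#' @inheritParams run_train
#' @param out Optional path; the evaluation report is written as JSON and
#'   ROC points as `<out>.roc.csv`.
#' @return An `eval_report`.
#' @export
run_jackknife <- function(features_csv, labels = NULL, config = run_config(),
                          out = NULL) {
  features <- if (is.data.frame(features_csv)) features_csv
              else read_csv_artifact(features_csv)
  y <- resolve_labels(features, labels)
  rep <- jackknife(features, y, C = config$C, gamma = config$gamma)
  if (!is.null(out)) {
    payload <- list(config_hash = config$hash,
                    counts = list(tp = rep$tp, tn = rep$tn, fp = rep$fp, fn = rep$fn),
                    metrics = list(sn = rep$sn, sp = rep$sp, acc = rep$acc,
                                   mcc = rep$mcc, auc = rep$auc))
    jsonlite::write_json(payload, out, auto_unbox = TRUE, digits = NA)
    write_roc_csv(rep, paste0(out, ".roc.csv"))
    return(invisible(rep))
  }
  rep
}

#' Train / apply the negative-subset ensemble
#'
#' Partitions the negative ids with the config seed, trains one member per
#' subset (each paired with all positives) and persists the ensemble.
#'
#' @inheritParams run_train
#' @param out Directory for the ensemble archive.
#' @return The `pseaac_ensemble`, invisibly when `out` is given.
#' @export
run_ensemble_train <- function(features_csv, labels = NULL,
                               config = run_config(), out = NULL) {
  features <- if (is.data.frame(features_csv)) features_csv
              else read_csv_artifact(features_csv)
  y <- resolve_labels(features, labels)
  pos <- features[y == 1, ]
  neg <- features[y == -1, ]
  parts <- partition_negatives(neg$seq_id, k = config$ensemble_k,
                               seed = config$seed)
  assignments <- setNames(rep(seq_along(parts), lengths(parts)),
                          unlist(parts))
  subsets <- purrr::map(parts, function(ids) neg[match(ids, neg$seq_id), ])
  ens <- train_ensemble(pos, subsets, C = config$C, gamma = config$gamma,
                        partition_seed = config$seed,
                        subset_assignments = assignments)
  if (!is.null(out)) {
    write_ensemble(ens, out)
    return(invisible(ens))
  }
  ens
}

#' @rdname run_ensemble_train
#' @param ensemble_dir Directory written by [run_ensemble_train()] (or a
#'   `pseaac_ensemble`).
#' @param features_csv Feature CSV or tibble to predict.
#' @export
run_ensemble_predict <- function(ensemble_dir, features_csv,
                                 config = run_config(), out = NULL) {
  ens <- if (inherits(ensemble_dir, "pseaac_ensemble")) ensemble_dir
         else read_ensemble(ensemble_dir)
  features <- if (is.data.frame(features_csv)) features_csv
              else read_csv_artifact(features_csv)
  res <- predict_ensemble(ens, features)
  if (!is.null(out)) {
    write_csv_artifact(as.data.frame(res), out, config)
    return(invisible(res))
  }
  res
}

#' Export the discriminant weight vector of a stored model
#'
#' @inheritParams run_predict
#' @return Tibble `feature`, `weight` (length `20 + lambda`).
#' @export
run_weights <- function(model_path, config = run_config(), out = NULL) {
  model <- if (inherits(model_path, "pseaac_svm")) model_path
           else read_model(model_path)
  w <- discriminant_weights(model)
  if (!is.null(out)) {
    write_csv_artifact(as.data.frame(w), out, config)
    return(invisible(w))
  }
  w
}

#' Scan jackknife performance over a (lambda, omega) grid
#'
#' Refeaturizes the consensus sequences at every `lambda` and jackknifes
#' each `(lambda, omega)` combination, reporting all metrics per grid
#' point — the standard way to choose the PseAAC operating point.
#'
#' @param sequences Tibble with `id`, `residues` (profile-consensus
#'   sequences) and `label` columns, or a FASTA path plus `labels` TSV.
#' @param lambdas,omegas Grid values.
#' @inheritParams run_train
#' @return Tibble with one row per grid point: `lambda`, `omega`, `sn`,
#'   `sp`, `acc`, `mcc`, `auc`.
#' @export
run_paramscan <- function(sequences, lambdas = 1:3, omegas = c(0.1, 0.5, 0.7),
                          labels = NULL, config = run_config(), out = NULL) {
  if (is.character(sequences)) {
    sequences <- read_fasta(sequences)
    sequences$label <- resolve_labels(
      tibble(seq_id = sequences$id), labels)
  }
  props <- config_properties(config)
  grid <- tidyr::expand_grid(lambda = lambdas, omega = omegas)
  res <- purrr::pmap(grid, function(lambda, omega) {
    feats <- featurize_batch(sequences, lambda = lambda, omega = omega,
                             props = props)
    rep <- jackknife(feats, sequences$label, C = config$C, gamma = config$gamma)
    glance(rep)[, c("sn", "sp", "acc", "mcc", "auc")]
  })
  scan <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  if (!is.null(out)) {
    write_csv_artifact(as.data.frame(scan), out, config)
    return(invisible(scan))
  }
  scan
}

#' Simulate a synthetic dataset to disk
#'
#' Writes FASTA sequences, PSI-BLAST-format PSSM files, a label manifest
#' TSV and a JSON run manifest for a [synthetic_spec()].
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory.
#' @param config A [run_config()] (for the recorded hash).
#' @return `dir`, invisibly.
#' @export
run_simulate <- function(spec, dir, config = run_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- generate_sequences(spec)
  write_fasta(seqs, file.path(dir, "sequences.fasta"))
  generate_profiles(seqs, spec, dir = file.path(dir, "pssm"))
  utils::write.table(data.frame(seq_id = seqs$id, label = seqs$label),
                     file.path(dir, "labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- c(list(config_hash = config$hash), unclass(spec))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
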