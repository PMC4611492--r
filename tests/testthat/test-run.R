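# End-to-end pipeline commands (the CLI's backing functions).

sim_dir <- local({
  dir <- tempfile("simfix")
  spec <- synthetic_spec(n_pos = 10, n_neg = 10, length_range = c(50, 80),
                         seed = 11)
  run_simulate(spec, dir, config = run_config())
  dir
})

test_that("simulate writes a complete, reproducible fixture directory", {
  expect_true(file.exists(file.path(sim_dir, "sequences.fasta")))
  expect_true(file.exists(file.path(sim_dir, "labels.tsv")))
  expect_true(file.exists(file.path(sim_dir, "manifest.json")))
  expect_length(list.files(file.path(sim_dir, "pssm"), pattern = "\\.pssm$"), 20)
  mf <- jsonlite::read_json(file.path(sim_dir, "manifest.json"))
  expect_equal(mf$seed, 11)
  expect_true(nzchar(mf$config_hash))
})

test_that("extract produces a deterministic 23-feature CSV from PSSM files", {
  cfg <- run_config()
  out1 <- tempfile(fileext = ".csv")
  feats <- run_extract(file.path(sim_dir, "sequences.fasta"),
                       profiles = file.path(sim_dir, "pssm"),
                       config = cfg, out = out1)
  expect_equal(ncol(feats) - 1, 23)  # 20 + lambda feature columns
  expect_equal(nrow(feats), 20)
  expect_equal(readLines(out1, n = 1), paste0("# config_hash: ", cfg$hash))

  out2 <- tempfile(fileext = ".csv")
  run_extract(file.path(sim_dir, "sequences.fasta"),
              profiles = file.path(sim_dir, "pssm"), config = cfg, out = out2)
  expect_identical(readLines(out1), readLines(out2))

  back <- propseaac:::read_csv_artifact(out1)
  expect_equal(as.matrix(back[, -1]), as.matrix(feats[, -1]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("extract reports missing profiles and honors --permissive", {
  fasta <- tempfile(fileext = ".fasta")
  seqs <- read_fasta(file.path(sim_dir, "sequences.fasta"))
  extra <- dplyr::bind_rows(seqs[1:3, ],
                            tibble::tibble(id = "orphan",
                                           residues = strrep("ACDEF", 12)))
  write_fasta(extra, fasta)
  out <- tempfile(fileext = ".csv")
  expect_error(run_extract(fasta, profiles = file.path(sim_dir, "pssm"),
                           config = run_config(), out = out),
               "orphan")
  expect_true(file.exists(paste0(out, ".failures.tsv")))

  expect_warning(
    feats <- run_extract(fasta, profiles = file.path(sim_dir, "pssm"),
                         config = run_config(), out = out, permissive = TRUE),
    "skipping")
  expect_equal(nrow(feats), 3)
})

test_that("extract builds profiles from alignments when no PSSM is given", {
  msa_dir <- tempfile("msa")
  dir.create(msa_dir)
  seqs <- read_fasta(file.path(sim_dir, "sequences.fasta"))[1:2, ]
  for (i in 1:2) {
    write_fasta(tibble::tibble(id = c("h1", "h2"),
                               residues = rep(seqs$residues[i], 2)),
                file.path(msa_dir, paste0(seqs$id[i], ".fasta")))
  }
  fasta <- tempfile(fileext = ".fasta")
  write_fasta(seqs, fasta)
  feats <- run_extract(fasta, msa = msa_dir, config = run_config())
  expect_equal(nrow(feats), 2)
  expect_equal(sum(unlist(feats[1, -1])), 1, tolerance = 1e-9)
})

test_that("train, predict, jackknife and weights close the loop on features", {
  cfg <- run_config()
  feat_csv <- tempfile(fileext = ".csv")
  run_extract(file.path(sim_dir, "sequences.fasta"),
              profiles = file.path(sim_dir, "pssm"), config = cfg,
              out = feat_csv)
  labels_tsv <- file.path(sim_dir, "labels.tsv")

  model_json <- tempfile(fileext = ".json")
  model <- run_train(feat_csv, labels = labels_tsv, config = cfg,
                     out = model_json)
  expect_true(file.exists(model_json))

  pred <- run_predict(model_json, feat_csv, config = cfg)
  lab <- utils::read.delim(labels_tsv)
  expect_equal(pred$label, lab$label[match(pred$seq_id, lab$seq_id)])

  rep_json <- tempfile(fileext = ".json")
  rep <- run_jackknife(feat_csv, labels = labels_tsv, config = cfg,
                       out = rep_json)
  payload <- jsonlite::read_json(rep_json)
  expect_equal(payload$metrics$acc, rep$acc)
  expect_true(file.exists(paste0(rep_json, ".roc.csv")))

  w <- run_weights(model_json, config = cfg)
  expect_equal(nrow(w), 23)
  expect_named(w, c("feature", "weight"))
})

test_that("ensemble training partitions negatives and persists the manifest", {
  spec <- synthetic_spec(n_pos = 12, n_neg = 48, seed = 12)
  d <- generate_dataset(spec)
  feats <- dplyr::mutate(d$features, label = d$labels)
  cfg <- run_config(overrides = list(ensemble_k = 4, seed = 12))
  dir <- tempfile("ensout")
  ens <- run_ensemble_train(feats, config = cfg, out = dir)
  expect_length(ens$members, 4)
  expect_equal(sort(unname(table(ens$subset_assignments))), rep(12, 4),
               ignore_attr = TRUE)
  pred <- run_ensemble_predict(dir, feats, config = cfg)
  expect_equal(nrow(pred), 60)
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
})

test_that("paramscan evaluates the full lambda-omega grid", {
  spec <- synthetic_spec(n_pos = 8, n_neg = 8, length_range = c(50, 70),
                         seed = 13)
  seqs <- generate_sequences(spec)
  scan <- run_paramscan(seqs, lambdas = 1:3, omegas = c(0.1, 0.5, 0.7),
                        config = run_config())
  expect_equal(nrow(scan), 9)
  expect_named(scan, c("lambda", "omega", "sn", "sp", "acc", "mcc", "auc"))
  expect_true(all(scan$acc >= 0 & scan$acc <= 100))
})

test_that("config resolution is flags over file over defaults", {
  cfg <- run_config()
  expect_equal(cfg$lambda, 3)
  expect_equal(cfg$omega, 0.7)
  expect_equal(cfg$C, 8192)
  expect_equal(cfg$gamma, 8.0)
  expect_equal(cfg$ensemble_k, 4)

  tf <- tempfile(fileext = ".cfg")
  writeLines(c("lambda = 2", "omega = 0.5  # comment", "", "C = 16"), tf)
  cfg <- run_config(tf)
  expect_equal(cfg$lambda, 2)
  expect_equal(cfg$omega, 0.5)
  expect_equal(cfg$C, 16)
  expect_equal(cfg$gamma, 8.0)

  cfg <- run_config(tf, overrides = list(omega = 0.9))
  expect_equal(cfg$omega, 0.9)
  expect_equal(cfg$lambda, 2)

  expect_error(run_config(tf, overrides = list(bogus = 1)),
               class = "propseaac_config_error")
  writeLines("omega = 2", tf)
  expect_error(run_config(tf), class = "propseaac_config_error")

  a <- run_config(overrides = list(seed = 1))
  b <- run_config(overrides = list(seed = 2))
  expect_false(a$hash == b$hash)
})

test_that("the command-line script runs end to end with proper exit codes", {
  rscript <- file.path(R.home("bin"), "Rscript")
  cli <- system.file("cli", "propseaac.R", package = "propseaac")
  expect_true(nzchar(cli))
  dir <- tempfile("clisim")

  st <- system2(rscript, c(cli, "simulate", "--n-pos", "4", "--n-neg", "4",
                           "--seed", "21", "--out", dir),
                stdout = TRUE, stderr = TRUE)
  expect_null(attr(st, "status"))
  expect_true(file.exists(file.path(dir, "sequences.fasta")))

  out_csv <- tempfile(fileext = ".csv")
  st <- system2(rscript, c(cli, "extract",
                           "--fasta", file.path(dir, "sequences.fasta"),
                           "--profiles", file.path(dir, "pssm"),
                           "--out", out_csv), stdout = TRUE, stderr = TRUE)
  expect_null(attr(st, "status"))
  feats <- propseaac:::read_csv_artifact(out_csv)
  expect_equal(ncol(feats) - 1, 23)

  # missing input -> exit 2; bad config value -> exit 3
  st <- suppressWarnings(
    system2(rscript, c(cli, "extract", "--fasta", "no-such-file.fasta",
                       "--out", tempfile()), stdout = TRUE, stderr = TRUE))
  expect_equal(attr(st, "status"), 2L)
  st <- suppressWarnings(
    system2(rscript, c(cli, "extract", "--omega", "3",
                       "--fasta", file.path(dir, "sequences.fasta"),
                       "--out", tempfile()), stdout = TRUE, stderr = TRUE))
  expect_equal(attr(st, "status"), 3L)
})
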