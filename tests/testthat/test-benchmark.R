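test_that("benchmark reports have full-factorial records and aggregates", {
  cfg <- quick_cfg(max_iter = 30)
  rep <- run_benchmark("sphere", algorithms = c("ssa", "issa"),
                       cfg = cfg, seeds = 1:3, d = 2)
  runs <- tidy(rep)
  expect_equal(nrow(runs), 6)  # 1 objective x 2 algorithms x 3 seeds
  expect_setequal(unique(runs$arm), c("ssa", "issa"))
  # aggregates are recomputable from the records
  gl <- glance(rep)
  for (r in seq_len(nrow(gl))) {
    sub <- runs$final_fitness[runs$arm == gl$arm[r]]
    expect_equal(gl$median_final[r], stats::median(sub))
    expect_equal(gl$n_runs[r], length(sub))
  }
  # identical call reproduces the report exactly
  rep2 <- run_benchmark("sphere", algorithms = c("ssa", "issa"),
                        cfg = cfg, seeds = 1:3, d = 2)
  expect_identical(tidy(rep), tidy(rep2))
  # paired counts partition the seed set
  pc <- paired_comparison(rep, "ssa", "issa")
  expect_equal(pc$wins_a + pc$losses_a + pc$ties, pc$n_pairs)
  expect_equal(pc$n_pairs, 3)
  expect_s3_class(autoplot(rep), "ggplot")
  # long histories unnest to T rows per run
  long <- tidy(rep, histories = TRUE)
  expect_equal(nrow(long), 6 * 30)
})

test_that("initializer ablation pairs both arms on every seed", {
  rep <- ablate_initializer("rastrigin", cfg = quick_cfg(max_iter = 30),
                            seeds = 1:3, d = 3)
  runs <- tidy(rep)
  expect_equal(nrow(runs), 6)
  counts <- table(runs$arm)
  expect_equal(as.integer(counts[c("issa_gps", "issa_random")]), c(3, 3))
  # reproducible rerun
  rep2 <- ablate_initializer("rastrigin", cfg = quick_cfg(max_iter = 30),
                             seeds = 1:3, d = 3)
  expect_identical(tidy(rep), tidy(rep2))
})

test_that("problem/solution/result files round-trip losslessly", {
  tmp <- withr::local_tempdir()
  fx <- random_linear_problem(4, seed = 55)
  stem <- file.path(tmp, "prob")
  write_allocation_problem(fx$prob, stem)
  back <- read_allocation_problem(stem)
  expect_equal(back$targets$efficiency, fx$prob$targets$efficiency)
  expect_equal(back$delta_sq, fx$prob$delta_sq)
  expect_equal(back$category, fx$prob$category)
  sol <- solve_allocation(back, quick_cfg(max_iter = 40))
  write_allocation_solution(sol, file.path(tmp, "sol"))
  shares <- utils::read.csv(file.path(tmp, "sol.csv"))
  expect_equal(shares$share, sol$x)
  js <- jsonlite::read_json(file.path(tmp, "sol.json"),
                            simplifyVector = TRUE)
  expect_equal(js$objective_value, sol$objective_value)
  expect_equal(js$balance, sol$balance)
  # optimizer result JSON carries the history verbatim
  res <- run_ssa(make_test_objective("sphere", 2),
                 search_space(-1, 1, d = 2), quick_cfg(max_iter = 10))
  write_optimization_result(res, file.path(tmp, "res.json"))
  rj <- jsonlite::read_json(file.path(tmp, "res.json"),
                            simplifyVector = TRUE)
  expect_equal(rj$history, res$history)
  expect_equal(rj$n_evaluations, res$n_evaluations)
  # point-set CSV: one row per point, no header
  write_point_set(good_point_set(5, 2), file.path(tmp, "pts.csv"))
  pts <- utils::read.csv(file.path(tmp, "pts.csv"), header = FALSE)
  expect_equal(as.matrix(pts), good_point_set(5, 2)$points,
               ignore_attr = TRUE)
})

test_that("config files parse with validation", {
  tmp <- withr::local_tempdir()
  yml <- file.path(tmp, "cfg.yaml")
  writeLines(c("pop_size: 12", "max_iter: 25", "seed: 4",
               "algorithm: issa"), yml)
  cfg <- read_optimizer_config(yml)
  expect_equal(cfg$pop_size, 12L)
  expect_equal(cfg$max_iter, 25L)
  expect_equal(attr(cfg, "algorithm"), "issa")
  jsn <- file.path(tmp, "cfg.json")
  jsonlite::write_json(list(pop_size = 8, max_iter = 10), jsn,
                       auto_unbox = TRUE)
  expect_equal(read_optimizer_config(jsn)$pop_size, 8L)
  writeLines("popsize: 3", yml)
  expect_error(read_optimizer_config(yml), "unknown configuration")
})

test_that("the CLI pipeline simulate -> optimize -> score works end-to-end", {
  tmp <- withr::local_tempdir()
  simdir <- file.path(tmp, "scenario")
  expect_equal(suppressMessages(
    cli_main(c("simulate", "--n-regions", "4", "--seed", "3",
               "--out", simdir))), 0L)
  expect_setequal(list.files(simdir),
                  c(outer(c("R1", "R2", "R3", "R4"), c(".csv", ".json"),
                          paste0)))
  cfgfile <- file.path(tmp, "cfg.yaml")
  writeLines(c("pop_size: 20", "max_iter: 40", "seed: 2"), cfgfile)
  out1 <- file.path(tmp, "sol1")
  expect_equal(suppressMessages(
    cli_main(c("optimize", "--problem", file.path(simdir, "R1"),
               "--config", cfgfile, "--out", out1))), 0L)
  sol <- jsonlite::read_json(paste0(out1, ".json"), simplifyVector = TRUE)
  expect_true(all(unlist(sol$feasible)))
  # same config + seed reproduces byte-identical outputs
  out2 <- file.path(tmp, "sol2")
  suppressMessages(
    cli_main(c("optimize", "--problem", file.path(simdir, "R1"),
               "--config", cfgfile, "--out", out2)))
  expect_identical(readLines(paste0(out1, ".json")),
                   readLines(paste0(out2, ".json")))
  expect_identical(readLines(paste0(out1, ".csv")),
                   readLines(paste0(out2, ".csv")))
  # satisfaction scoring prints JSON
  scored <- file.path(tmp, "score.json")
  expect_equal(suppressMessages(
    cli_main(c("score", "--satisfaction", "8,6", "--weights", "0.7,0.3",
               "--out", scored))), 0L)
  expect_equal(jsonlite::read_json(scored)$satisfaction, 7.4)
})

test_that("the CLI reports usage and infeasibility errors by exit code", {
  # unknown subcommand and missing options are usage errors (2)
  expect_equal(suppressMessages(cli_main("frobnicate")), 2L)
  expect_equal(suppressMessages(cli_main(c("optimize", "--out", "x"))), 2L)
  # an infeasible problem (variance cap below 1/n) exits 1 and names
  # the constraint
  tmp <- withr::local_tempdir()
  stem <- file.path(tmp, "bad")
  utils::write.csv(data.frame(target_id = c("a", "b", "c"),
                              efficiency = c(1, 2, 3),
                              weight = rep(1 / 3, 3),
                              g_family = "linear", g_param = NA,
                              lb = 0, ub = 1),
                   paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(n = 3, delta_sq = 0.2, category = "R1",
                            shareable = TRUE),
                       paste0(stem, ".json"), auto_unbox = TRUE)
  msgs <- character()
  code <- withCallingHandlers(
    cli_main(c("optimize", "--problem", stem, "--out",
               file.path(tmp, "sol"))),
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  expect_equal(code, 1L)
  expect_true(any(grepl("variance cap", msgs)))
})
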