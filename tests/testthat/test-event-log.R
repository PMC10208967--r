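write_log <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c("subject,session,time_s,kind", lines), path)
  path
}

test_that("a small log parses into one sorted, validated record", {
  path <- write_log(c("m1,d1,2.5,lick", "m1,d1,1.0,active_poke",
                      "m1,d1,2.0,lick"))
  recs <- read_event_log(path)
  expect_length(recs, 1)
  rec <- recs[["m1/d1"]]
  expect_s3_class(rec, "event_record")
  expect_equal(nrow(rec$events), 3)
  expect_equal(rec$events$time_s, c(1.0, 2.0, 2.5))
  expect_equal(rec$events$kind, c("active_poke", "lick", "lick"))
})

test_that("an empty log yields an empty collection", {
  expect_equal(read_event_log(write_log(character(0))), list())
})

test_that("structural violations are rejected with informative errors", {
  # event beyond session duration
  path <- write_log("m1,d1,3601,lick")
  expect_error(read_event_log(path, duration_s = 3600),
               class = "starpheno_validation_error")
  # missing required column
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject,time_s,kind", "m1,1,lick"), path2)
  expect_error(read_event_log(path2), class = "starpheno_schema_error")
  # malformed rows are reported with line numbers
  path3 <- write_log(c("m1,d1,1.0,lick", "m1,d1,oops,lick",
                       "m1,d1,2.0,press"))
  expect_error(read_event_log(path3), "3, 4",
               class = "starpheno_parse_error")
  # sipper events must alternate starting with extend
  expect_error(
    event_record("m1", "d1", data.frame(
      time_s = c(1, 2), kind = c("sipper_retract", "sipper_extend"))),
    class = "starpheno_validation_error")
  expect_error(
    event_record("m1", "d1", data.frame(
      time_s = c(1, 2), kind = c("sipper_extend", "sipper_extend"))),
    class = "starpheno_validation_error")
})

test_that("lickometer debouncing collapses chatter but keeps real licks", {
  path <- write_log(c("m1,d1,1.000,lick", "m1,d1,1.005,lick",
                      "m1,d1,1.200,lick", "m1,d1,0.5,active_poke"))
  recs <- read_event_log(path, debounce_s = 0.02)
  ev <- recs[["m1/d1"]]$events
  expect_equal(sum(ev$kind == "lick"), 2)       # 1.005 collapsed into 1.000
  expect_equal(sum(ev$kind == "active_poke"), 1)
  # off by default
  recs2 <- read_event_log(path)
  expect_equal(sum(recs2[["m1/d1"]]$events$kind == "lick"), 3)
})

test_that("session summaries count events and compute intake", {
  rec <- event_record("m1", "d1", data.frame(
    time_s = c(sort(runif(30, 0, 3000)),               # active pokes
               100, 110, 200, 210, 300, 310,           # 3 access windows
               sort(runif(120, 0, 3600))),             # licks
    kind = c(rep("active_poke", 30),
             rep(c("sipper_extend", "sipper_retract"), 3),
             rep("lick", 120))))
  s <- summarize_session(rec, session_index = 1, epoch = "phenotyping",
                         condition = "alcohol_only",
                         consumed_volume_mL = 0.5, weight_g = 25)
  expect_equal(s$active_responses, 30)
  expect_equal(s$reinforcers, 3)
  expect_equal(s$licks, 120)
  expect_equal(s$intake_gkg, compute_intake_gkg(0.5, 0.15, 25))
})

test_that("dry sessions have zero intake regardless of volume bookkeeping", {
  rec <- event_record("m1", "cr1", data.frame(time_s = 1, kind = "active_poke"))
  s <- summarize_session(rec, condition = "dry", consumed_volume_mL = 0.2,
                         weight_g = 25)
  expect_equal(s$intake_gkg, 0)
})

test_that("summarize_sessions joins metadata by subject and session", {
  path <- write_log(c("m1,d1,1.0,active_poke", "m2,d1,2.0,lick"))
  recs <- read_event_log(path)
  meta <- data.frame(subject = c("m1", "m2"), session = "d1",
                     session_index = 1, epoch = "phenotyping",
                     condition = "alcohol_only",
                     consumed_volume_mL = c(0.4, 0.2), weight_g = 25)
  out <- summarize_sessions(recs, meta)
  expect_equal(nrow(out), 2)
  expect_equal(out$licks, c(0, 1))
  expect_error(summarize_sessions(recs, meta[1, ]),
               class = "starpheno_schema_error")
})
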