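Package: screenbouts
Title: Screen-On Bout Detection and Daily Screen-Time Measures from
    Smartphone State Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning passively collected smartphone power-state
    logs (lock/unlock events on iOS, screen on/off events on Android, plus
    iOS battery-level telemetry) into screen-on bouts, per-minute and
    per-day data-validity labels, daily screen-time measures (total
    screen-on time, on/off bout durations, bout counts), and minute-level
    binary phone-use profiles suitable for functional analyses such as
    daylight-saving-time natural experiments. Includes a ground-truthed
    synthetic log simulator so every pipeline stage can be exercised
    without participant data, and a command-line interface over the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    zoo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
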