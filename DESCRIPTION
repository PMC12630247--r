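Package: reidkit
Title: Offline Re-Identification and Pose Annotation for Multi-Person
    Behavioural Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating video recordings of a known number of
    freely moving people. Per-frame appearance embeddings are clustered
    into exactly K identities (k-means with k-means++ seeding), a
    per-frame uniqueness check flags or optimally resolves identity
    collisions, and numeric clusters are mapped to semantic labels.
    Includes skeleton-based sitting/standing classification with
    leave-one-session-out evaluation, behavioural analytics (centroid
    trajectories, pose event intervals, per-session joint-variance
    trends), scoring against ground truth, audits of external track
    files for identity over-detection, and a synthetic session
    generator so the whole pipeline is testable without video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    withr,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
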