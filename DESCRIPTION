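Package: penaltypose
Title: Body-Orientation and Strategy Analytics for Penalty Kicks from 2D Pose Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives body-orientation and goalkeeper-anticipation metrics from
    25-landmark 2D pose-estimator keypoints via a field homography estimated by
    the direct linear transformation, integrates them with an observational
    (notational) coding scheme for penalty kicks (OSPAF), and runs the strategy
    association analysis: chi-squared tests with Cramer's V effect sizes,
    point-biserial correlations, test-retest reliability bands, and
    enter-method logistic regression with classification accuracy. Includes a
    synthetic scene and dataset generator with known ground truth so the whole
    pipeline is testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
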