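"""Batch fit/predict worker for the RF and SVM backends.

Reads a job directory containing:
  job.json  -- {"model": "rf"|"svm", "labels": [...0/1...],
                "tasks": [{"id", "params", "kernel", "train", "test",
                           "seed"}, ...]}
  X.txt     -- one 0/1 bitstring per instance (row order = labels order)
  K.txt     -- optional precomputed Tanimoto Gram matrix (space-separated
               rows), required for SVM tasks with kernel == "tanimoto"

and writes result.json: {"results": [{"id", "pred", "score"}, ...]}.
Indices in "train"/"test" are 1-based (R convention). The worker only
fits scikit-learn estimators on data prepared upstream; it performs no
splitting, selection or evaluation.
"""
import json
import os
import sys

import numpy as np
from sklearn.ensemble import RandomForestClassifier
from sklearn.svm import SVC


def load_bitstrings(path):
    rows = []
    with open(path) as fh:
        for line in fh:
            line = line.strip()
            if line:
                rows.append(np.frombuffer(line.encode(), dtype=np.uint8) - 48)
    return np.asarray(rows, dtype=np.uint8)


def main(job_dir):
    with open(os.path.join(job_dir, "job.json")) as fh:
        job = json.load(fh)
    y = np.asarray(job["labels"], dtype=np.int64)
    x_path = os.path.join(job_dir, "X.txt")
    k_path = os.path.join(job_dir, "K.txt")
    X = load_bitstrings(x_path) if os.path.exists(x_path) else None
    K = np.loadtxt(k_path) if os.path.exists(k_path) else None
    if K is not None and K.ndim == 1:
        K = K.reshape(1, -1)

    results = []
    for task in job["tasks"]:
        tr = np.asarray(task["train"], dtype=np.int64) - 1
        te = np.asarray(task["test"], dtype=np.int64) - 1
        params = task.get("params") or {}
        seed = int(task.get("seed", 0))
        if job["model"] == "rf":
            clf = RandomForestClassifier(
                n_estimators=int(params["n_estimators"]),
                min_samples_split=int(params["min_samples_split"]),
                random_state=seed,
                n_jobs=1,
            )
            clf.fit(X[tr], y[tr])
            pred = clf.predict(X[te])
            pos = list(clf.classes_).index(1)
            score = clf.predict_proba(X[te])[:, pos]
        elif job["model"] == "svm":
            C = float(params["C"])
            if task["kernel"] == "tanimoto":
                clf = SVC(C=C, kernel="precomputed", random_state=seed)
                clf.fit(K[np.ix_(tr, tr)], y[tr])
                dec = clf.decision_function(K[np.ix_(te, tr)])
                pred = clf.predict(K[np.ix_(te, tr)])
            else:
                clf = SVC(C=C, kernel="linear", random_state=seed)
                clf.fit(X[tr], y[tr])
                dec = clf.decision_function(X[te])
                pred = clf.predict(X[te])
            # decision_function is oriented toward classes_[1]
            score = dec if clf.classes_[1] == 1 else -dec
        else:
            raise ValueError("unknown model " + str(job["model"]))
        results.append({
            "id": task["id"],
            "pred": [int(v) for v in pred],
            "score": [float(v) for v in score],
        })

    with open(os.path.join(job_dir, "result.json"), "w") as fh:
        json.dump({"results": results}, fh)


if __name__ == "__main__":
    main(sys.argv[1])
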