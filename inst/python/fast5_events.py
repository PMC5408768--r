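#!/usr/bin/env python
"""Dump the event table of a pre-basecalled FAST5 (HDF5) file as TSV.

Usage: fast5_events.py input.fast5 output.tsv

Searches a list of candidate HDF5 paths for an EventDetection-style
events table (columns start, length, mean, stdv); start/length given in
raw sample counts are converted to seconds using the channel sampling
rate. Prints '#read_id=<id>' on stdout when an id attribute is found.
"""
import sys

import h5py
import numpy as np

CANDIDATE_GROUPS = [
    "/Analyses/EventDetection_000/Reads",
    "/Analyses/EventDetection_001/Reads",
]
CANDIDATE_TABLES = [
    "/Raw/Reads",  # some files keep events next to the raw read
]


def find_events(f):
    for g in CANDIDATE_GROUPS + CANDIDATE_TABLES:
        if g not in f:
            continue
        grp = f[g]
        for read_name in grp:
            node = grp[read_name]
            if "Events" in node:
                return node["Events"], node
    # flat fallback: any dataset literally called Events
    found = []

    def visit(name, obj):
        if isinstance(obj, h5py.Dataset) and name.endswith("Events"):
            found.append(obj)

    f.visititems(visit)
    if found:
        return found[0], found[0].parent
    return None, None


def main(argv):
    if len(argv) != 3:
        sys.stderr.write(__doc__)
        return 2
    with h5py.File(argv[1], "r") as f:
        events, node = find_events(f)
        if events is None:
            sys.stderr.write("no events table found in %s\n" % argv[1])
            return 1
        tab = events[()]
        cols = {}
        for c in ("start", "length", "mean", "stdv"):
            if c not in tab.dtype.names:
                sys.stderr.write("events table lacks column %s\n" % c)
                return 1
            cols[c] = np.asarray(tab[c], dtype=float)
        rate = None
        for holder in (node, f.get("/UniqueGlobalKey/channel_id")):
            if holder is None:
                continue
            for key in ("sampling_rate", "sample_rate"):
                if key in holder.attrs:
                    rate = float(holder.attrs[key])
        # integer-typed start/length indicates raw sample units
        raw_units = np.issubdtype(tab.dtype["start"], np.integer)
        if raw_units:
            if rate is None:
                sys.stderr.write("raw-unit events but no sampling rate\n")
                return 1
            cols["start"] = cols["start"] / rate
            cols["length"] = cols["length"] / rate
        if "read_id" in node.attrs:
            rid = node.attrs["read_id"]
            if isinstance(rid, bytes):
                rid = rid.decode()
            sys.stdout.write("#read_id=%s\n" % rid)
        with open(argv[2], "w") as out:
            out.write("start\tlength\tmean\tstdv\n")
            for i in range(len(cols["start"])):
                out.write("%.17g\t%.17g\t%.17g\t%.17g\n" % (
                    cols["start"][i], cols["length"][i],
                    cols["mean"][i], cols["stdv"][i]))
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
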