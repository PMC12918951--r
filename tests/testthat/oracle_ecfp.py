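#!/usr/bin/env python3
"""Independent reimplementation of the package's folded Morgan fingerprint.

Reads a JSON list of molecular graphs ({"atoms": [...], "bonds": [...]}) and
prints, per molecule, the sorted set bit indices (comma-separated). The
algorithm follows the documented specification: FNV-1a (32-bit) hashing of
little-endian integer bytes; initial atom invariants (z, degree, charge+16,
nH, ring, aromatic); per round r = 1..radius the identifier is rehashed with
the sorted (bond-code, neighbor-identifier) pairs; isolated atoms keep their
identifier; all identifiers are folded modulo nbits.
"""
import json
import sys

FNV_OFFSET = 2166136261
FNV_PRIME = 16777619


def fnv1a32(ints):
    h = FNV_OFFSET
    for v in ints:
        x = int(v) % (1 << 32)
        for _ in range(4):
            h = ((h ^ (x & 0xFF)) * FNV_PRIME) % (1 << 32)
            x >>= 8
    return h


def fingerprint(graph, radius, nbits):
    atoms = graph["atoms"]
    bonds = graph["bonds"]
    n = len(atoms)
    ids = [
        fnv1a32([a["z"], a["degree"], a["charge"] + 16, a["nh"],
                 a["ring"], a["aromatic"]])
        for a in atoms
    ]
    nbr = [[] for _ in range(n)]
    for b in bonds:
        nbr[b["i"] - 1].append((b["code"], b["j"] - 1))
        nbr[b["j"] - 1].append((b["code"], b["i"] - 1))
    all_ids = list(ids)
    for r in range(1, radius + 1):
        new_ids = []
        for a in range(n):
            if not nbr[a]:
                new_ids.append(ids[a])
                continue
            pairs = sorted((code, ids[other]) for code, other in nbr[a])
            seq = [r, ids[a]]
            for code, ident in pairs:
                seq.extend([code, ident])
            new_ids.append(fnv1a32(seq))
        ids = new_ids
        all_ids.extend(ids)
    return sorted({i % nbits for i in all_ids})


def main():
    payload = json.load(open(sys.argv[1]))
    radius = payload["radius"]
    nbits = payload["nbits"]
    for graph in payload["graphs"]:
        bits = fingerprint(graph, radius, nbits)
        print(",".join(str(b) for b in bits))


if __name__ == "__main__":
    main()
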