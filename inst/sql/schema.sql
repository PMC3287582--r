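-- Relational schema of the process repository (RDBMS-independent DDL).
-- The package's file-backed store materialises exactly these tables, one CSV
-- per table; deploying against a server RDBMS uses this migration unchanged.

CREATE TABLE process_definition (
    name       VARCHAR(128) NOT NULL,
    version    INTEGER      NOT NULL CHECK (version >= 1),
    npdl_text  TEXT         NOT NULL,
    PRIMARY KEY (name, version)
);

CREATE TABLE procedure_catalog (
    name        VARCHAR(128) PRIMARY KEY,
    description TEXT,
    technique   TEXT,
    reagents    TEXT           -- free-text list, ';'-separated
);

CREATE TABLE test (
    name          VARCHAR(128) PRIMARY KEY,
    description   TEXT,
    duration_days NUMERIC CHECK (duration_days >= 0),
    cost          NUMERIC CHECK (cost >= 0),
    process_name  VARCHAR(128) NOT NULL   -- latest compiled process
);

CREATE TABLE test_item (
    test       VARCHAR(128) NOT NULL REFERENCES test(name),
    procedure  VARCHAR(128) NOT NULL REFERENCES procedure_catalog(name),
    exec_order INTEGER      NOT NULL CHECK (exec_order >= 1),
    PRIMARY KEY (test, procedure)
);

CREATE TABLE patient (
    number INTEGER PRIMARY KEY,
    name   TEXT NOT NULL
);

CREATE TABLE sample (
    dna_number VARCHAR(32) PRIMARY KEY,
    patient    INTEGER NOT NULL REFERENCES patient(number)
);

CREATE TABLE test_order (
    id           INTEGER PRIMARY KEY,
    sample       VARCHAR(32)  NOT NULL REFERENCES sample(dna_number),
    test         VARCHAR(128) NOT NULL REFERENCES test(name),
    request_date TEXT NOT NULL          -- ISO-8601
);

CREATE TABLE instance (
    id            VARCHAR(64) PRIMARY KEY,
    order_id      INTEGER NOT NULL REFERENCES test_order(id),
    residual_npdl TEXT NOT NULL,        -- always reparsable
    lifecycle     VARCHAR(16) NOT NULL
        CHECK (lifecycle IN ('running','finished','forced_finished',
                             'canceled','stuck'))
);

CREATE TABLE event (
    instance  VARCHAR(64) NOT NULL REFERENCES instance(id),
    seq       INTEGER     NOT NULL,
    action    VARCHAR(128),
    status    VARCHAR(16) NOT NULL
        CHECK (status IN ('released','completed','repeated',
                          'test_canceled','test_finished')),
    outcome   VARCHAR(8) CHECK (outcome IN ('ok','failed')),
    timestamp TEXT NOT NULL,            -- ISO-8601
    PRIMARY KEY (instance, seq)
);
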